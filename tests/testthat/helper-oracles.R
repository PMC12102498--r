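suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# ---- independent patristic oracle: shortest paths on the tree graph ----
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  ord <- match(as.character(seq_len(n_tip)), rownames(d))
  m <- d[ord, ord]
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

# ---- independent alignment oracle: pointer-based three-state DP --------
# Same contract as the package aligner (BLOSUM62; gap of length L costs
# open + L * ext; tie preference M > X > Y) but implemented with forward
# predecessor pointers instead of backward score recomputation.
oracle_align <- function(a, b, open = 11, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sub <- e$BLOSUM62
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  open1 <- open + ext
  NEG <- -1e15
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  PM <- PX <- PY <- matrix(0L, n + 1, m + 1) # predecessor state 1/2/3
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (i in seq_len(n)[-1]) PX[i + 1, 1] <- 2L
  if (n > 0) PX[2, 1] <- 1L
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (j in seq_len(m)[-1]) PY[1, j + 1] <- 3L
  if (m > 0) PY[1, 2] <- 1L
  best3 <- function(vm, vx, vy) {
    # returns c(value, argstate) with preference M > X > Y on ties
    v <- max(vm, vx, vy)
    s <- if (vm >= vx && vm >= vy) 1L else if (vx >= vy) 2L else 3L
    c(v, s)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[ca[i], cb[j]]
      r <- best3(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- s + r[1]
      PM[i + 1, j + 1] <- r[2]
      r <- best3(M[i, j + 1] - open1, X[i, j + 1] - ext,
                 Y[i, j + 1] - open1)
      X[i + 1, j + 1] <- r[1]
      PX[i + 1, j + 1] <- r[2]
      r <- best3(M[i + 1, j] - open1, X[i + 1, j] - open1,
                 Y[i + 1, j] - ext)
      Y[i + 1, j + 1] <- r[1]
      PY[i + 1, j + 1] <- r[2]
    }
  }
  r <- best3(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  score <- r[1]
  state <- r[2]
  al_a <- character(0)
  al_b <- character(0)
  i <- n
  j <- m
  while (i > 0 || j > 0) {
    if (i == 0) state <- 3L
    if (j == 0) state <- 2L
    if (state == 1) {
      al_a <- c(ca[i], al_a)
      al_b <- c(cb[j], al_b)
      state <- PM[i + 1, j + 1]
      i <- i - 1
      j <- j - 1
    } else if (state == 2) {
      al_a <- c(ca[i], al_a)
      al_b <- c("-", al_b)
      state <- PX[i + 1, j + 1]
      i <- i - 1
    } else {
      al_a <- c("-", al_a)
      al_b <- c(cb[j], al_b)
      state <- PY[i + 1, j + 1]
      j <- j - 1
    }
  }
  list(score = score, aligned_a = paste(al_a, collapse = ""),
       aligned_b = paste(al_b, collapse = ""))
}

oracle_identity <- function(a, b, open = 11, ext = 1) {
  al <- oracle_align(a, b, open, ext)
  xa <- strsplit(al$aligned_a, "")[[1]]
  xb <- strsplit(al$aligned_b, "")[[1]]
  gap <- xa == "-" | xb == "-"
  if (all(gap)) return(0)
  span <- min(which(!gap)):max(which(!gap))
  100 * sum(xa[span] == xb[span] & xa[span] != "-") / length(span)
}

# ---- brute-force pilin array oracle ------------------------------------
# enumerates every candidate run of pilin positions and keeps valid,
# maximal ones
oracle_arrays <- function(pilin_idx, max_spacer = 1, min_size = 2) {
  pilin_idx <- sort(pilin_idx)
  runs <- list()
  np <- length(pilin_idx)
  for (i in seq_len(np)) {
    for (j in i:np) {
      members <- pilin_idx[i:j]
      valid <- j == i || all(diff(members) <= max_spacer + 1)
      if (!valid) next
      left_ext <- i > 1 && (members[1] - pilin_idx[i - 1]) <= max_spacer + 1
      right_ext <- j < np && (pilin_idx[j + 1] - members[j - i + 1]) <=
        max_spacer + 1
      if (!left_ext && !right_ext && length(members) >= min_size) {
        runs[[length(runs) + 1]] <- members
      }
    }
  }
  runs
}

# ---- fixture builders ---------------------------------------------------
make_cds <- function(n, assembly = "A1", contig = "c1", aa = NULL) {
  tibble(
    assembly_id = assembly,
    contig_id = contig,
    contig_length = n * 1000L + 100L,
    protein_id = sprintf("%s_%s_p%03d", assembly, contig, seq_len(n)),
    index = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+",
    aa_seq = aa %||% NA_character_
  )
}

make_calls <- function(protein_id, category) {
  tibble(protein_id = protein_id, category = category,
         profile_set = "SET", profile_name = "prof",
         bitscore = 100)
}

make_hit <- function(protein_id = "p1", profile_set = "MPF_FATA",
                     profile_name = "PrgI", profile_length = 100L,
                     i_evalue = 1e-10, bitscore = 100,
                     hmm_from = 1L, hmm_to = 90L) {
  tibble(protein_id = protein_id, profile_set = profile_set,
         profile_name = profile_name,
         profile_length = as.integer(profile_length),
         i_evalue = i_evalue, bitscore = bitscore,
         hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to))
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# component calls from a simulated bundle, restricted (as the pipeline
# does) to profiles present in the shipped mapping
t4ss_calls <- function(sim) {
  mp <- component_mapping()
  h <- dplyr::semi_join(sim$hits, mp, by = c("profile_set", "profile_name"))
  assign_components(filter_hits(h), mapping = mp)
}

mutate_test_seq <- function(seq, n_sub) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  chars[pos] <- vapply(chars[pos], function(cur) sample(setdiff(aa, cur), 1),
                       character(1))
  paste(chars, collapse = "")
}

`%||%` <- rlang::`%||%`
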