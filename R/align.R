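# Affine-gap global alignment (Gotoh) over BLOSUM62.
#
# Scoring: substitution from BLOSUM62; a gap of length L costs
# gap_open + L * gap_extend (opening a gap therefore costs open + extend
# for its first residue). Traceback is deterministic: at equal scores the
# preference is diagonal (match state) > gap in the second sequence >
# gap in the first, applied both to state selection and to predecessor
# selection. The tie-break is part of the function's contract — identity
# of co-optimal alignments depends on it.

.anchorscan_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.anchorscan_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .anchorscan_env$BLOSUM62 <- e$BLOSUM62
  }
  .anchorscan_env$BLOSUM62
}

seq_to_int <- function(s) {
  sub <- blosum62()
  cs <- strsplit(s, "")[[1]]
  idx <- match(cs, rownames(sub))
  if (anyNA(idx)) {
    rlang::abort(sprintf("residue(s) not in BLOSUM62: %s",
                         paste(unique(cs[is.na(idx)]), collapse = ", ")))
  }
  idx
}

# fast path: alignment statistics from integer-encoded sequences
align_stats_int <- function(ai, bi, gap_open = 11, gap_extend = 1) {
  res <- .gotoh_align_cpp(ai, bi, blosum62(), gap_open + gap_extend,
                          gap_extend)
  oa <- res$a
  ob <- res$b
  nz <- which(oa != 0L & ob != 0L)
  if (length(nz) == 0) {
    return(list(score = res$score, pct_id = 0, alignment_length = 0L,
                cov_a = 0, cov_b = 0, a = oa, b = ob))
  }
  span <- nz[1]:nz[length(nz)]
  list(score = res$score,
       pct_id = 100 * sum(oa[span] == ob[span] & oa[span] != 0L) /
         length(span),
       alignment_length = length(span),
       cov_a = sum(oa[span] != 0L) / length(ai),
       cov_b = sum(ob[span] != 0L) / length(bi),
       a = oa, b = ob)
}

align_global <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) rlang::abort("empty sequence")
  res <- .gotoh_align_cpp(seq_to_int(a), seq_to_int(b), blosum62(),
                          gap_open + gap_extend, gap_extend)
  gapped <- c("-", rownames(blosum62()))
  list(score = res$score,
       aligned_a = paste(gapped[res$a + 1L], collapse = ""),
       aligned_b = paste(gapped[res$b + 1L], collapse = ""))
}

#' Global alignment statistics for two protein sequences
#'
#' Aligns two amino-acid sequences globally (affine gaps over BLOSUM62, gap
#' open 11, extend 1; a length-L gap costs open + L × extend) and reports
#' percent identity and mutual coverage. Identity uses the full alignment
#' length including internal gaps but excluding terminal-gap overhangs;
#' coverage of each sequence is the fraction of its residues inside the
#' overhang-trimmed alignment.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1).
#' @return One-row tibble: `score`, `pct_id`, `alignment_length`, `cov_a`,
#'   `cov_b`, `aligned_a`, `aligned_b`.
#' @export
align_stats <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) rlang::abort("empty sequence")
  st <- align_stats_int(seq_to_int(a), seq_to_int(b),
                        gap_open = gap_open, gap_extend = gap_extend)
  gapped <- c("-", rownames(blosum62()))
  tibble::tibble(score = st$score, pct_id = st$pct_id,
                 alignment_length = st$alignment_length,
                 cov_a = st$cov_a, cov_b = st$cov_b,
                 aligned_a = paste(gapped[st$a + 1L], collapse = ""),
                 aligned_b = paste(gapped[st$b + 1L], collapse = ""))
}

#' Percent amino-acid identity of two sequences
#'
#' Convenience scalar wrapper around [align_stats()]: global alignment
#' identity with the denominator being the alignment length including
#' internal gaps, excluding terminal-gap overhangs. Identical sequences
#' give exactly 100.
#'
#' @inheritParams align_stats
#' @return Percent identity in \[0, 100\].
#' @examples
#' pairwise_identity("ACDE", "ACDF") # 75
#' @export
pairwise_identity <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) rlang::abort("empty sequence")
  if (identical(a, b)) return(100)
  align_stats_int(seq_to_int(a), seq_to_int(b), gap_open = gap_open,
                  gap_extend = gap_extend)$pct_id
}

#' Greedy incremental sequence clustering
#'
#' Simplified greedy clustering at fixed identity and coverage thresholds:
#' sequences are processed by decreasing length (ties by protein id); each
#' sequence joins the earliest-founded cluster whose representative it
#' matches at `min_id` identity and `min_cov` bidirectional coverage or
#' founds a new cluster. Clusters with more than `profile_min_members`
#' members are flagged profile-eligible (the size at which a cluster
#' alignment is worth turning into a search profile). This is a
#' deterministic stand-in for external clustering tools, not an equivalent.
#'
#' @param seqs Tibble with `protein_id`, `aa_seq` (rows without a sequence
#'   are dropped).
#' @param min_id Minimum fractional identity to the representative
#'   (default 0.30, inclusive).
#' @param min_cov Minimum coverage of both member and representative
#'   (default 0.70, inclusive).
#' @param profile_min_members Strict lower bound on member count for the
#'   profile-eligible flag (default 5, i.e. > 5 members).
#' @return Tibble with one row per sequence: `cluster_id`,
#'   `representative`, `protein_id`, `pct_id_to_rep`, `cov_member`,
#'   `cov_rep`, `n_members`, `profile_eligible`.
#' @export
greedy_cluster <- function(seqs, min_id = 0.30, min_cov = 0.70,
                           profile_min_members = 5) {
  check_columns(seqs, c("protein_id", "aa_seq"), "`seqs`")
  seqs <- seqs |>
    dplyr::filter(!is.na(.data$aa_seq)) |>
    dplyr::arrange(dplyr::desc(nchar(.data$aa_seq)), .data$protein_id)
  ints <- lapply(seqs$aa_seq, seq_to_int)
  lens <- lengths(ints)
  reps <- character(0)
  rep_idx <- integer(0)
  rows <- vector("list", nrow(seqs))
  for (r in seq_len(nrow(seqs))) {
    pid <- seqs$protein_id[r]
    assigned <- NA_integer_
    stats <- NULL
    for (ci in seq_along(reps)) {
      # processing order is by decreasing length, so the representative is
      # never shorter than the member: when the member is too short to
      # span min_cov of the representative, no alignment can qualify
      if (lens[r] < min_cov * lens[rep_idx[ci]]) next
      st <- align_stats_int(ints[[r]], ints[[rep_idx[ci]]])
      if (st$pct_id / 100 >= min_id && st$cov_a >= min_cov &&
          st$cov_b >= min_cov) {
        assigned <- ci
        stats <- st
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, pid)
      rep_idx <- c(rep_idx, r)
      assigned <- length(reps)
      stats <- list(pct_id = 100, cov_a = 1, cov_b = 1)
    }
    rows[[r]] <- tibble::tibble(
      cluster_id = assigned, representative = reps[assigned],
      protein_id = pid, pct_id_to_rep = stats$pct_id,
      cov_member = stats$cov_a, cov_rep = stats$cov_b
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(n_members = dplyr::n(),
                  profile_eligible = dplyr::n() > profile_min_members) |>
    dplyr::ungroup()
}

#' Write profile-eligible cluster members as FASTA files
#'
#' One FASTA per profile-eligible cluster (named after its representative),
#' ready for external alignment and profile construction.
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param seqs Tibble with `protein_id`, `aa_seq`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_cluster_fasta <- function(clusters, seqs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eligible <- dplyr::filter(clusters, .data$profile_eligible)
  paths <- vapply(split(eligible, eligible$cluster_id), function(cl) {
    members <- dplyr::semi_join(seqs, cl, by = "protein_id")
    path <- file.path(dir, paste0("cluster_", cl$representative[1], ".faa"))
    write_protein_fasta(members, path)
    path
  }, character(1))
  invisible(unname(paths))
}
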