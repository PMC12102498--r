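#' Configuration for the synthetic dataset generator
#'
#' Bundles every knob of [simulate_dataset()] with defaults that emulate a
#' draft-quality phylum survey: most genomes carry one T4SS gene cluster, a
#' small fraction of anchor genes sit near a contig end, component genes
#' co-occur near the anchor with category-specific probabilities, some
#' clusters sit near the replication origin (a dnaA-marked CDS), pilin
#' arrays of 2–11 genes occur in a minority of T4SS genomes, and hit tables
#' carry decoys straddling the filter thresholds (half failing on
#' i-Evalue, half on coverage, including exact-boundary cases).
#'
#' @param seed Integer seed; per-genome sub-seeds are derived
#'   deterministically from it.
#' @param n_classes Number of taxonomic classes.
#' @param genomes_per_class Genomes per class.
#' @param cds_per_genome Length-2 integer range for the CDS count per
#'   genome (default 300–2300, matching ~1 CDS/kb over 0.3–2.3 Mb
#'   assemblies).
#' @param t4ss_presence_prob Probability a genome carries T4SS cluster(s).
#' @param t4ss_clusters_per_genome Clusters planted per T4SS genome.
#' @param k Window radius used to define "near" (default 20).
#' @param near_end_rate Probability an anchor is planted with fewer than
#'   `k` CDS to a contig end (the contig is cut accordingly).
#' @param near_origin_prob Probability the (first) cluster is planted
#'   within `k` CDS of the dnaA-marked origin CDS.
#' @param component_composition Tibble with `category` and `prob`: per-
#'   category probability that a cluster contains that component within
#'   ±10 CDS of the anchor.
#' @param t4cp_far_prob Probability a genome carries a T4CP gene far from
#'   any anchor.
#' @param relaxase_far_prob Probability of a far relaxase gene.
#' @param pilin_array_prob Probability a T4SS genome carries a pilin array.
#' @param pilin_array_sizes Integer vector of possible array sizes.
#' @param pilin_array_size_probs Probabilities over `pilin_array_sizes`
#'   (normalised internally).
#' @param spacer_prob Probability that two consecutive array members are
#'   separated by one non-pilin gene rather than tandem.
#' @param decoy_hit_rate Expected decoy hits per CDS (0 disables decoys).
#' @param qc_fail_rate Fraction of genomes planted to fail the quality
#'   gate.
#' @param emit_sequences Generate amino-acid sequences for all proteins
#'   (pilin-array members always get sequences).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_classes = 4,
                       genomes_per_class = 6,
                       cds_per_genome = c(300L, 2300L),
                       t4ss_presence_prob = 0.8,
                       t4ss_clusters_per_genome = 1,
                       k = 20,
                       near_end_rate = 0.052,
                       near_origin_prob = 0.5,
                       component_composition = NULL,
                       t4cp_far_prob = 0.9,
                       relaxase_far_prob = 0.03,
                       pilin_array_prob = 0.18,
                       pilin_array_sizes = 2:11,
                       pilin_array_size_probs = 2^-(0:9),
                       spacer_prob = 0.3,
                       decoy_hit_rate = 0.005,
                       qc_fail_rate = 0.1,
                       emit_sequences = TRUE) {
  if (is.null(component_composition)) {
    component_composition <- tibble::tibble(
      category = c("TrsD", "VirB2", "VirB3", "PrgF", "VirB6", "VirB1",
                   "T4CP", "VirB8", "VirB9", "Relaxase_MOBC"),
      prob = c(0.67, 0.55, 0.36, 0.25, 0.12, 0.05, 0.06, 0.01, 0.005, 0.006)
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_classes = n_classes,
    genomes_per_class = genomes_per_class,
    cds_per_genome = as.integer(cds_per_genome),
    t4ss_presence_prob = t4ss_presence_prob,
    t4ss_clusters_per_genome = t4ss_clusters_per_genome,
    k = k, near_end_rate = near_end_rate,
    near_origin_prob = near_origin_prob,
    component_composition = component_composition,
    t4cp_far_prob = t4cp_far_prob, relaxase_far_prob = relaxase_far_prob,
    pilin_array_prob = pilin_array_prob,
    pilin_array_sizes = pilin_array_sizes,
    pilin_array_size_probs =
      pilin_array_size_probs / sum(pilin_array_size_probs),
    spacer_prob = spacer_prob, decoy_hit_rate = decoy_hit_rate,
    qc_fail_rate = qc_fail_rate, emit_sequences = emit_sequences
  )
  probs <- c(t4ss_presence_prob, near_end_rate, near_origin_prob,
             pilin_array_prob, qc_fail_rate, spacer_prob,
             component_composition$prob)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("probabilities must be in [0, 1]")
  }
  # each cluster needs its window plus room for a far-placed pilin array
  if (cfg$cds_per_genome[1] <
      (cfg$t4ss_clusters_per_genome - 1) * (2 * k + 40) + (k + 25) +
      (k + 95) + 1) {
    rlang::abort("infeasible config: clusters larger than the smallest genome")
  }
  structure(cfg, class = "sim_config")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n_seq, lengths) {
  total <- sum(lengths)
  chars <- sample(AA20, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  vapply(seq_len(n_seq), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

mutate_seq <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  chars[pos] <- vapply(chars[pos], function(cur) {
    sample(setdiff(AA20, cur), 1)
  }, character(1))
  paste(chars, collapse = "")
}

# identity of substitution-only paralogs, by direct position comparison
planted_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  100 * sum(ca == cb) / length(ca)
}

# a passing hit against a given profile row
passing_hit <- function(protein_id, profile_row) {
  plen <- sample(100:600, 1)
  cov <- runif(1, 0.55, 0.98)
  span <- ceiling(cov * plen)
  from <- sample(plen - span + 1, 1)
  tibble::tibble(
    protein_id = protein_id,
    profile_set = profile_row$profile_set,
    profile_name = profile_row$profile_name,
    profile_length = plen,
    i_evalue = 10^runif(1, -20, -4),
    bitscore = round(runif(1, 50, 300), 1),
    hmm_from = as.integer(from), hmm_to = as.integer(from + span - 1)
  )
}

#' Simulate a full survey dataset with ground truth
#'
#' Generates annotated genomes (CDS tables and, optionally, GFF3 + protein
#' FASTA files), profile hit tables (domtblout dialect), a taxonomy/QC
#' table and a complete truth table. Deterministic given `cfg$seed`:
#' rerunning with the same config produces identical outputs.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, all input formats are
#'   written there (per-assembly `.gff3`/`.faa`, `hits_<set>.domtblout`,
#'   `taxonomy_qc.tsv`, `truth_*.tsv`).
#' @return A list of class `t4ss_sim`: `cds`, `qc`, `hits` (all profile
#'   sets combined), `truth` (list of tibbles: `proteins`, `hits`,
#'   `anchors`, `windows`, `arrays`), and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  mapping <- component_mapping()
  map_by_cat <- split(mapping, mapping$category)
  n_genomes <- cfg$n_classes * cfg$genomes_per_class
  classes <- sprintf("class_%02d", rep(seq_len(cfg$n_classes),
                                       each = cfg$genomes_per_class))
  k <- cfg$k

  all_cds <- vector("list", n_genomes)
  all_hits <- vector("list", n_genomes)
  all_qc <- vector("list", n_genomes)
  tp <- vector("list", n_genomes)   # truth: proteins
  th <- vector("list", n_genomes)   # truth: hit pass/fail
  ta <- vector("list", n_genomes)   # truth: anchors
  tw <- vector("list", n_genomes)   # truth: windows
  tarr <- vector("list", n_genomes) # truth: arrays

  for (g in seq_len(n_genomes)) {
    set.seed(derive_subseed(cfg$seed, g))
    asm <- sprintf("ASM%04d", g)
    n <- sample(seq(cfg$cds_per_genome[1], cfg$cds_per_genome[2]), 1)
    pid <- sprintf("%s_p%05d", asm, seq_len(n))

    has_t4ss <- runif(1) < cfg$t4ss_presence_prob
    n_clusters <- if (has_t4ss) cfg$t4ss_clusters_per_genome else 0
    spacing <- 2 * k + 40
    base <- if (n_clusters > 0) {
      sample(seq(k + 25, n - (k + 95) - (n_clusters - 1) * spacing), 1)
    } else {
      NA_integer_
    }
    anchor_pos0 <- if (n_clusters > 0) base + (seq_len(n_clusters) - 1) *
      spacing else integer(0) # 0-based pre-cut positions

    # origin: dnaA-marked CDS; first cluster may be planted near it
    # (upstream side, outside the +-10 component zone)
    near_origin <- n_clusters > 0 && runif(1) < cfg$near_origin_prob
    dnaa_pos <- if (near_origin) {
      anchor_pos0[1] + sample(-16:-11, 1)
    } else {
      d <- sample(seq(5L, n - 6L), 1)
      while (n_clusters > 0 && min(abs(d - anchor_pos0)) <= 2 * k) {
        d <- sample(seq(5L, n - 6L), 1)
      }
      d
    }
    dnan_pos <- dnaa_pos + 1L

    genome_hits <- list()
    proteins_truth <- list()
    windows_truth <- list()
    anchors_truth <- list()
    arrays_truth <- list()
    occupied <- c(dnaa_pos, dnan_pos)
    pilin_seq <- rep(NA_character_, n)

    add_call <- function(pos, category) {
      row <- map_by_cat[[category]][
        sample(nrow(map_by_cat[[category]]), 1), ]
      genome_hits[[length(genome_hits) + 1]] <<-
        passing_hit(pid[pos + 1], row)
      proteins_truth[[length(proteins_truth) + 1]] <<- tibble::tibble(
        assembly_id = asm, protein_id = pid[pos + 1], category = category)
    }

    cuts <- integer(0) # contig cut AFTER this 0-based position
    for (ci in seq_len(n_clusters)) {
      apos <- anchor_pos0[ci]
      add_call(apos, "VirB4")
      occupied <- c(occupied, apos)
      # the fragmentation cut never severs the +-10 component zone, so a
      # near-end anchor keeps its planted companions but loses window slots
      near_end <- runif(1) < cfg$near_end_rate
      if (near_end) {
        d_end <- sample(min(11, k - 1):(k - 1), 1)
        cuts <- c(cuts, apos + d_end)
      }
      comp <- cfg$component_composition
      incl <- runif(nrow(comp)) < comp$prob
      free <- setdiff(apos + c(-10:-1, 1:10), occupied)
      offs <- sample(free, min(sum(incl), length(free)))
      cats <- comp$category[incl][seq_along(offs)]
      for (ii in seq_along(offs)) {
        add_call(offs[ii], cats[ii])
        windows_truth[[length(windows_truth) + 1]] <- tibble::tibble(
          assembly_id = asm, anchor_protein = pid[apos + 1],
          offset = offs[ii] - apos, category = cats[ii])
      }
      occupied <- c(occupied, offs)
      anchors_truth[[length(anchors_truth) + 1]] <- tibble::tibble(
        assembly_id = asm, anchor_protein = pid[apos + 1],
        near_end = near_end,
        dist_to_end_planted = if (near_end) d_end else NA_integer_,
        near_origin = ci == 1 && near_origin,
        n_companions = length(offs))

      # pilin array for the first cluster: inside the window when the
      # contig is intact, otherwise beyond the cut (arrays never straddle
      # the planted fragmentation point)
      if (ci == 1 && runif(1) < cfg$pilin_array_prob) {
        size <- sample(cfg$pilin_array_sizes, 1,
                       prob = cfg$pilin_array_size_probs)
        near_anchor <- !near_end && runif(1) < 0.5
        start <- if (near_anchor) apos + 13L else apos + 40L
        gaps <- 1L + (runif(size - 1) < cfg$spacer_prob)
        positions <- start + c(0L, cumsum(gaps))
        anc <- random_aa(1, 55L)
        members <- vapply(seq_len(size), function(i) {
          mutate_seq(anc, round(55 * runif(1, 0.05, 0.25)))
        }, character(1))
        pilin_seq[positions + 1] <- members
        for (i in seq_len(size)) add_call(positions[i], "VirB2")
        occupied <- c(occupied, positions,
                      setdiff(seq(min(positions) - 2, max(positions) + 2),
                              positions))
        pairs <- utils::combn(size, 2)
        ids_pct <- apply(pairs, 2, function(p)
          planted_identity(members[p[1]], members[p[2]]))
        arrays_truth[[length(arrays_truth) + 1]] <- tibble::tibble(
          assembly_id = asm,
          first_index_precut = min(positions),
          member_ids = list(pid[positions + 1]),
          n_pilins = size,
          n_spacers = sum(gaps == 2L),
          mean_pct_id = mean(ids_pct), max_pct_id = max(ids_pct))
      }
    }

    # far components (away from every anchor window)
    far_slot <- function() {
      repeat {
        p <- sample(seq(0L, n - 1L), 1)
        ok <- !(p %in% occupied) &&
          (n_clusters == 0 || min(abs(p - anchor_pos0)) > 2 * k)
        if (ok) return(p)
      }
    }
    if (runif(1) < cfg$t4cp_far_prob) {
      p <- far_slot()
      add_call(p, "T4CP")
      occupied <- c(occupied, p)
    }
    if (runif(1) < cfg$relaxase_far_prob) {
      p <- far_slot()
      add_call(p, "Relaxase_MOBC")
      occupied <- c(occupied, p)
    }

    # decoy hits straddling the thresholds: half fail on i-Evalue,
    # half on coverage, first of each kind exactly on the boundary
    n_decoys <- round(cfg$decoy_hit_rate * n)
    if (n_decoys > 0) {
      free <- setdiff(seq(0L, n - 1L), occupied)
      dpos <- sample(free, min(n_decoys, length(free)))
      for (i in seq_along(dpos)) {
        row <- mapping[sample(nrow(mapping), 1), ]
        h <- passing_hit(pid[dpos[i] + 1], row)
        if (i %% 2 == 1) { # fail on i-Evalue (boundary first)
          h$i_evalue <- if (i == 1) 0.001 else runif(1, 0.001, 0.05)
        } else {           # fail on coverage (boundary first)
          plen <- if (i == 2) 200L else 2L * sample(60:300, 1)
          frac <- if (i == 2) 0.5 else runif(1, 0.25, 0.5)
          span <- floor(frac * plen)
          h$profile_length <- as.integer(plen)
          h$hmm_from <- 1L
          h$hmm_to <- as.integer(span)
        }
        genome_hits[[length(genome_hits) + 1]] <- h
      }
    }

    # functional-family hits on origin-region genes
    fun_hits <- dplyr::bind_rows(
      tibble::tibble(protein_id = pid[dnaa_pos + 1],
                     profile_set = c("NCBIFAM", "TIGRFAM"),
                     profile_name = c("dnaA", "TIGR00362")),
      tibble::tibble(protein_id = pid[dnan_pos + 1],
                     profile_set = c("NCBIFAM", "Pfam"),
                     profile_name = c("dnaN", "PF02767")),
      tibble::tibble(protein_id = pid[sample(n, 5)],
                     profile_set = "Pfam",
                     profile_name = sprintf("PF9%04d", sample(30, 5,
                                                              replace = TRUE)))
    ) |>
      dplyr::mutate(profile_length = 200L,
                    i_evalue = 10^runif(dplyr::n(), -20, -4),
                    bitscore = round(runif(dplyr::n(), 50, 300), 1),
                    hmm_from = 1L, hmm_to = 180L)
    genome_hits[[length(genome_hits) + 1]] <- fun_hits

    hits_g <- dplyr::bind_rows(genome_hits)
    # contig assignment from cuts
    cuts <- sort(unique(cuts))
    bounds <- c(-1L, cuts, n - 1L) # contig ci covers (bounds[ci], bounds[ci+1]]
    contig_of <- findInterval(seq(0L, n - 1L), bounds + 1L) # 1-based contig
    idx0 <- seq(0L, n - 1L)
    within <- idx0 - c(-1L, cuts)[contig_of] - 1L

    aa <- if (cfg$emit_sequences) {
      out <- random_aa(n, sample(80:300, n, replace = TRUE))
      out[!is.na(pilin_seq)] <- pilin_seq[!is.na(pilin_seq)]
      out
    } else {
      pilin_seq
    }

    all_cds[[g]] <- tibble::tibble(
      assembly_id = asm,
      contig_id = sprintf("%s_ctg%d", asm, contig_of),
      protein_id = pid,
      index = as.integer(within),
      start = within * 1000L + 1L,
      end = within * 1000L + 900L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      aa_seq = aa
    ) |>
      dplyr::group_by(.data$contig_id) |>
      dplyr::mutate(contig_length = max(.data$end) + 100L) |>
      dplyr::ungroup() |>
      dplyr::select("assembly_id", "contig_id", "contig_length",
                    "protein_id", "index", "start", "end", "strand",
                    "aa_seq")

    qc_fails <- runif(1) < cfg$qc_fail_rate
    all_qc[[g]] <- tibble::tibble(
      assembly_id = asm, class_label = classes[g],
      completeness = round(if (qc_fails) runif(1, 30, 50)
                           else runif(1, 75, 100), 2),
      contamination = round(runif(1, 0, 4), 2),
      planted_pass = !qc_fails
    )

    all_hits[[g]] <- hits_g
    th[[g]] <- dplyr::mutate(
      hits_g,
      should_pass = .data$i_evalue < 0.001 &
        (.data$hmm_to - .data$hmm_from + 1) / .data$profile_length > 0.5)
    tp[[g]] <- dplyr::bind_rows(proteins_truth)
    ta[[g]] <- dplyr::bind_rows(anchors_truth)
    tw[[g]] <- dplyr::bind_rows(windows_truth)
    tarr[[g]] <- dplyr::bind_rows(arrays_truth)
  }

  cds <- dplyr::bind_rows(all_cds)
  truth_arrays <- dplyr::bind_rows(tarr)
  # resolve planted array member ids to contig ids (post-cut)
  if (nrow(truth_arrays) > 0) {
    first_member <- tibble::tibble(
      protein_id = purrr::map_chr(truth_arrays$member_ids, 1))
    truth_arrays$contig_id <- dplyr::left_join(
      first_member, dplyr::select(cds, "protein_id", "contig_id"),
      by = "protein_id")$contig_id
  }

  sim <- structure(list(
    cds = cds,
    qc = dplyr::bind_rows(all_qc),
    hits = dplyr::bind_rows(all_hits),
    truth = list(
      proteins = dplyr::bind_rows(tp),
      hits = dplyr::bind_rows(th),
      anchors = dplyr::bind_rows(ta),
      windows = dplyr::bind_rows(tw),
      arrays = truth_arrays
    ),
    config = cfg
  ), class = "t4ss_sim")

  if (!is.null(dir)) write_sim_bundle(sim, dir)
  sim
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' @param sim A `t4ss_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (asm in unique(sim$cds$assembly_id)) {
    acds <- dplyr::filter(sim$cds, .data$assembly_id == asm)
    write_gff3(acds, file.path(dir, paste0(asm, ".gff3")))
    if (any(!is.na(acds$aa_seq))) {
      write_protein_fasta(acds, file.path(dir, paste0(asm, ".faa")))
    }
  }
  readr::write_tsv(
    dplyr::select(sim$qc, "assembly_id", "class_label", "completeness",
                  "contamination"),
    file.path(dir, "taxonomy_qc.tsv"))
  for (set in sort(unique(sim$hits$profile_set))) {
    write_domtblout(dplyr::filter(sim$hits, .data$profile_set == set),
                    file.path(dir, sprintf("hits_%s.domtblout", set)))
  }
  readr::write_tsv(sim$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  readr::write_tsv(sim$truth$anchors, file.path(dir, "truth_anchors.tsv"))
  readr::write_tsv(sim$truth$windows, file.path(dir, "truth_windows.tsv"))
  readr::write_tsv(sim$truth$hits, file.path(dir, "truth_hits.tsv"))
  if (nrow(sim$truth$arrays) > 0) {
    readr::write_tsv(
      dplyr::mutate(sim$truth$arrays,
                    member_ids = purrr::map_chr(.data$member_ids, paste,
                                                collapse = ",")),
      file.path(dir, "truth_arrays.tsv"))
  }
  invisible(dir)
}
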