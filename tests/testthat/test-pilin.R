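pilin_fixture <- function(pilin_idx, n = 20) {
  cds <- make_cds(n)
  calls <- make_calls(cds$protein_id[pilin_idx + 1], "VirB2")
  list(cds = cds, calls = calls)
}

test_that("arrays allow one spacer but split on two", {
  # P P x P -> one array of 3 with a recorded spacer
  f <- pilin_fixture(c(5, 6, 8))
  arr <- detect_arrays(f$cds, f$calls)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$n_pilins, 3L)
  expect_equal(arr$spacer_positions[[1]], 7L)
  expect_equal(arr$n_spacers, 1L)

  # P x x P -> no array
  f2 <- pilin_fixture(c(5, 8))
  expect_equal(nrow(detect_arrays(f2$cds, f2$calls)), 0)

  # arrays never span contigs
  cds <- bind_rows(make_cds(10, contig = "c1"), make_cds(10, contig = "c2"))
  calls <- make_calls(cds$protein_id[c(9, 10, 11, 12)], "VirB2")
  arr3 <- detect_arrays(cds, calls)
  expect_equal(nrow(arr3), 2)
  expect_true(all(arr3$n_pilins == 2))
})

test_that("detected arrays equal the exhaustive enumeration oracle", {
  set.seed(99)
  for (r in 1:60) {
    n <- sample(10:40, 1)
    pidx <- sort(sample(0:(n - 1), sample(2:8, 1)))
    f <- pilin_fixture(pidx, n = n)
    got <- detect_arrays(f$cds, f$calls)
    want <- oracle_arrays(pidx)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(
        unname(lapply(got$member_indices, as.integer)),
        unname(lapply(want, as.integer)))
      # disjoint and conserved membership
      all_members <- unlist(got$member_indices)
      expect_equal(anyDuplicated(all_members), 0L)
      expect_true(all(all_members %in% pidx))
    }
  }
})

test_that("pairwise identity matches its definition on forced alignments", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  expect_error(pairwise_identity("", "ACDE"), "empty")
})

test_that("identity is symmetric and self-identity is exactly 100", {
  set.seed(7)
  for (r in 1:15) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 100)
  }
})

test_that("alignment scores agree with an established aligner", {
  set.seed(13)
  for (r in 1:20) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    st <- align_stats(a, b)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global")
    expect_equal(st$score, Biostrings::score(ref))
  }
})

test_that("array identity statistics cover all member pairs", {
  cds <- make_cds(6, aa = NA_character_)
  cds$aa_seq <- c("MKVLAWTTE", "MKVLAWTTE", "MKVLAWTTE",
                  "MKVAAWTTE", NA, NA)
  calls <- make_calls(cds$protein_id[1:4], "VirB2")
  arr <- detect_arrays(cds, calls)
  st <- array_identity_stats(arr, cds)
  expect_equal(st$max_pct_id, 100)
  # pairs: three identical pairs (100) and three pairs with 1/9 mismatch
  expect_equal(st$mean_pct_id, mean(c(100, 100, 100, rep(100 * 8 / 9, 3))))

  two <- detect_arrays(cds[4:6, ] |>
                         dplyr::mutate(index = 0:2),
                       make_calls(cds$protein_id[4:5], "VirB2"))
  expect_error(array_identity_stats(two, cds), "missing sequence")
})

test_that("greedy clustering respects thresholds, order and the size flag", {
  set.seed(21)
  anc1 <- random_protein(60)
  anc2 <- random_protein(60)
  fam1 <- c(anc1, vapply(1:5, function(i) mutate_test_seq(anc1, 8),
                         character(1)))
  fam2 <- c(anc2, vapply(1:4, function(i) mutate_test_seq(anc2, 8),
                         character(1)))
  seqs <- tibble(
    protein_id = sprintf("s%02d", seq_len(11)),
    aa_seq = c(fam1, fam2)
  )
  cl <- greedy_cluster(seqs)
  expect_equal(length(unique(cl$cluster_id)), 2)
  sizes <- cl |> dplyr::count(cluster_id)
  expect_setequal(sizes$n, c(6L, 5L))
  # > 5 members flags profile eligibility; exactly 5 does not
  expect_true(all(cl$profile_eligible[cl$cluster_id ==
                                        sizes$cluster_id[sizes$n == 6]]))
  expect_false(any(cl$profile_eligible[cl$cluster_id ==
                                         sizes$cluster_id[sizes$n == 5]]))
  # post-hoc: every member satisfies both thresholds vs its representative
  reps <- setNames(seqs$aa_seq, seqs$protein_id)
  for (r in seq_len(nrow(cl))) {
    st <- align_stats(reps[[cl$protein_id[r]]], reps[[cl$representative[r]]])
    expect_gte(st$pct_id / 100, 0.30)
    expect_gte(st$cov_a, 0.70)
    expect_gte(st$cov_b, 0.70)
  }
  # determinism
  expect_equal(greedy_cluster(seqs), cl)
  # only the >5-member cluster yields a profile-building FASTA
  fa_dir <- withr::local_tempdir()
  paths <- write_cluster_fasta(cl, seqs, fa_dir)
  expect_equal(length(paths), 1)
  expect_equal(nrow(read_protein_fasta(paths[1])), 6)
  # all-identical input collapses to one cluster
  same <- tibble(protein_id = c("a", "b", "c"), aa_seq = anc1)
  expect_equal(unique(greedy_cluster(same)$cluster_id), 1L)
})
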