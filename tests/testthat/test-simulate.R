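small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_classes = 2, genomes_per_class = 3,
             cds_per_genome = c(300L, 400L), ...)
}

test_that("the generator is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_cfg(), dir = d1)
  simulate_dataset(small_cfg(), dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
})

test_that("generated files parse cleanly back through the readers", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(), dir = d)
  asm <- unique(sim$cds$assembly_id)[1]
  back <- read_genome_annotation(file.path(d, paste0(asm, ".gff3")),
                                 file.path(d, paste0(asm, ".faa")))
  orig <- sim$cds[sim$cds$assembly_id == asm, ]
  m <- inner_join(orig, back, by = "protein_id", suffix = c("", ".rt"))
  expect_equal(nrow(m), nrow(orig))
  expect_equal(m$index, m$index.rt)
  expect_equal(m$contig_id, m$contig_id.rt)
  expect_equal(m$start, m$start.rt)
  expect_equal(m$aa_seq, m$aa_seq.rt)
  qc <- read_taxonomy_qc(file.path(d, "taxonomy_qc.tsv"))
  expect_setequal(qc$assembly_id, unique(sim$qc$assembly_id))
  doms <- list.files(d, pattern = "domtblout$", full.names = TRUE)
  hits <- bind_rows(lapply(doms, function(f) {
    read_domtblout(f, sub("^hits_(.*)\\.domtblout$", "\\1", basename(f)))
  }))
  expect_equal(nrow(hits), nrow(sim$hits))
})

test_that("truth table and generated data are mutually consistent", {
  sim <- simulate_dataset(small_cfg())
  expect_true(all(sim$truth$proteins$protein_id %in% sim$cds$protein_id))
  expect_true(all(sim$truth$hits$protein_id %in% sim$cds$protein_id))
  expect_true(all(unlist(sim$truth$arrays$member_ids) %in%
                    sim$cds$protein_id))
  # every planted component has a hit that passes the filters
  planted <- sim$truth$proteins$protein_id
  passing <- filter_hits(sim$hits)$protein_id
  expect_true(all(planted %in% passing))
})

test_that("with no decoys, filtering recovers exactly the planted categories", {
  sim <- simulate_dataset(small_cfg(seed = 3, decoy_hit_rate = 0))
  calls <- t4ss_calls(sim)
  got <- paste(calls$protein_id, calls$category)
  want <- paste(sim$truth$proteins$protein_id,
                sim$truth$proteins$category)
  expect_setequal(got, want)
})

test_that("decoys straddle both thresholds and all fail", {
  sim <- simulate_dataset(small_cfg(seed = 5, decoy_hit_rate = 0.02))
  truth <- sim$truth$hits
  decoys <- truth[!truth$should_pass, ]
  expect_gt(nrow(decoys), 0)
  cov <- (decoys$hmm_to - decoys$hmm_from + 1) / decoys$profile_length
  fail_e <- decoys$i_evalue >= 0.001
  fail_c <- cov <= 0.5
  expect_true(all(fail_e | fail_c))
  expect_true(any(fail_e) && any(fail_c))
  # exact boundary hits are planted and must be excluded by strictness
  expect_true(any(decoys$i_evalue == 0.001))
  expect_true(any(cov == 0.5))
  kept <- filter_hits(sim$hits)
  key <- function(h) paste(h$protein_id, h$profile_set, h$profile_name,
                           h$i_evalue, h$hmm_from, h$hmm_to)
  expect_setequal(key(kept), key(truth[truth$should_pass, ]))
})

test_that("planted near-end anchors are exactly the truncated ones", {
  sim <- simulate_dataset(small_cfg(seed = 9, near_end_rate = 0.4))
  tr <- anchor_truncation(sim$cds, sim$truth$anchors$anchor_protein, k = 20)
  m <- inner_join(sim$truth$anchors, tr, by = "anchor_protein")
  expect_equal(nrow(m), nrow(sim$truth$anchors))
  expect_equal(m$near_end.x, m$near_end.y)
  planted <- m[m$near_end.x, ]
  if (nrow(planted) > 0) {
    expect_equal(planted$dist_to_end, planted$dist_to_end_planted)
  }
})

test_that("planted window composition is recovered around each anchor", {
  sim <- simulate_dataset(small_cfg(seed = 13))
  w <- extract_neighborhoods(sim$cds, sim$truth$anchors$anchor_protein,
                             k = 20)
  calls <- t4ss_calls(sim)
  got <- w |>
    inner_join(calls[, c("protein_id", "category")], by = "protein_id",
               relationship = "many-to-many") |>
    filter(offset != 0, !category %in% c("VirB4", "Other", "VirB2")) |>
    select(anchor_protein, offset, category)
  want <- sim$truth$windows |>
    filter(category != "VirB2") |>
    select(anchor_protein, offset, category)
  expect_setequal(paste(got$anchor_protein, got$offset, got$category),
                  paste(want$anchor_protein, want$offset, want$category))
})

test_that("planted pilin arrays are recovered with their identity stats", {
  sim <- simulate_dataset(small_cfg(seed = 2, pilin_array_prob = 1,
                                    t4ss_presence_prob = 1))
  calls <- t4ss_calls(sim)
  arr <- detect_arrays(sim$cds, calls)
  truth <- sim$truth$arrays
  expect_equal(nrow(arr), nrow(truth))
  key <- function(ids) vapply(ids, paste, character(1), collapse = ",")
  arr <- arr[order(key(arr$member_ids)), ]
  truth <- truth[order(key(truth$member_ids)), ]
  expect_equal(key(arr$member_ids), key(truth$member_ids))
  expect_equal(arr$n_pilins, truth$n_pilins)
  expect_equal(arr$n_spacers, truth$n_spacers)
  st <- array_identity_stats(arr, sim$cds)
  expect_equal(st$mean_pct_id, truth$mean_pct_id, tolerance = 1e-9)
  expect_equal(st$max_pct_id, truth$max_pct_id, tolerance = 1e-9)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(cds_per_genome = c(100L, 200L)), "infeasible")
  expect_error(sim_config(t4ss_presence_prob = 1.2), "probabilities")
})

test_that("simulated trees honour planted transfers and zero pairs", {
  s0 <- simulate_labelled_tree(n_leaves = 80, n_classes = 3,
                               transfer_fraction = 0, n_zero_pairs = 3,
                               seed = 4)
  g0 <- glance(provenance_analysis(s0$tree, s0$labels))
  expect_equal(g0$n_closest_diff, 0)
  expect_equal(g0$n_identical_same_class, 6) # both members of each pair

  s2 <- simulate_labelled_tree(n_leaves = 80, n_classes = 3,
                               transfer_fraction = 0.2, seed = 4)
  g2 <- glance(provenance_analysis(s2$tree, s2$labels))
  expect_equal(g2$n_closest_diff, sum(s2$truth$is_transfer))
  expect_equal(sum(s2$truth$is_transfer), round(0.2 * 80))

  expect_error(simulate_labelled_tree(transfer_fraction = 1), "transfer_fraction")

  # newick round-trip preserves topology and branch lengths
  f <- tempfile(fileext = ".nwk")
  simulate_labelled_tree(n_leaves = 30, n_classes = 2, seed = 8, path = f)
  s3 <- simulate_labelled_tree(n_leaves = 30, n_classes = 2, seed = 8)
  back <- read_virb4_tree(f)
  expect_true(ape::all.equal.phylo(back$tree, s3$tree,
                                   use.edge.length = FALSE))
  m1 <- patristic_matrix(s3$tree)
  m2 <- patristic_matrix(back$tree)[rownames(m1), colnames(m1)]
  expect_equal(m2, m1, tolerance = 1e-9)
})
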