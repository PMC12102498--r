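test_that("window extraction yields offsets, truncation flags and degenerate cases", {
  cds <- make_cds(100)
  a25 <- cds$protein_id[26] # index 25
  w <- extract_neighborhoods(cds, a25, k = 20)
  expect_equal(w$offset, -20:20)
  tr <- anchor_truncation(cds, a25, k = 20)
  expect_true(is.na(tr$upstream_truncated_at))
  expect_true(is.na(tr$downstream_truncated_at))
  expect_false(tr$near_end)

  a3 <- cds$protein_id[4] # index 3
  w3 <- extract_neighborhoods(cds, a3, k = 20)
  expect_equal(min(w3$offset), -3)
  tr3 <- anchor_truncation(cds, a3, k = 20)
  expect_equal(tr3$upstream_truncated_at, -3)
  expect_true(tr3$near_end)

  solo <- make_cds(1, contig = "solo")
  ws <- extract_neighborhoods(solo, solo$protein_id, k = 20)
  expect_equal(ws$offset, 0)

  expect_error(extract_neighborhoods(cds, "nope"), "not found")
})

test_that("window extraction is translation-invariant away from contig ends", {
  cds <- make_cds(200)
  offs <- lapply(c(60, 100, 140), function(i) {
    extract_neighborhoods(cds, cds$protein_id[i + 1], k = 20)$offset
  })
  expect_equal(offs[[1]], offs[[2]])
  expect_equal(offs[[2]], offs[[3]])
})

test_that("windows never span contigs", {
  cds <- bind_rows(make_cds(30, contig = "c1"), make_cds(30, contig = "c2"))
  a <- cds$protein_id[cds$contig_id == "c1"][28] # index 27, near c1 end
  w <- extract_neighborhoods(cds, a, k = 20)
  expect_true(all(w$contig_id == "c1"))
  expect_equal(max(w$offset), 2)
})

test_that("companion filter needs a non-anchor T4SS component in the window", {
  cds <- make_cds(50)
  anchor <- cds$protein_id[26]
  w <- extract_neighborhoods(cds, anchor, k = 20)

  keep <- anchors_with_companion(
    w, bind_rows(make_calls(anchor, "VirB4"),
                 make_calls(cds$protein_id[27], "TrsD")))
  expect_equal(unique(keep$anchor_protein), anchor)

  drop_unannotated <- anchors_with_companion(
    w, make_calls(anchor, "VirB4"))
  expect_equal(nrow(drop_unannotated), 0)

  # a second VirB4 copy is not "another T4SS component"
  drop_second_virb4 <- anchors_with_companion(
    w, bind_rows(make_calls(anchor, "VirB4"),
                 make_calls(cds$protein_id[30], "VirB4")))
  expect_equal(nrow(drop_second_virb4), 0)

  # and an Other call never counts
  drop_other <- anchors_with_companion(
    w, bind_rows(make_calls(anchor, "VirB4"),
                 make_calls(cds$protein_id[27], "Other")))
  expect_equal(nrow(drop_other), 0)
})

test_that("positional abundance counts per anchor and per category", {
  cds <- make_cds(60)
  anchor <- cds$protein_id[31]
  calls <- bind_rows(
    make_calls(anchor, "VirB4"),
    make_calls(cds$protein_id[30], "VirB3"), # offset -1
    make_calls(cds$protein_id[33], "VirB6")  # offset +2
  )
  w <- extract_neighborhoods(cds, anchor, k = 20)
  pa <- positional_abundance(w, calls)
  expect_equal(pa$n[pa$offset == -1 & pa$category == "VirB3"], 1L)
  expect_equal(pa$n[pa$offset == 2 & pa$category == "VirB6"], 1L)
  expect_equal(pa$pct[pa$offset == -1], 100)
  expect_equal(attr(pa, "anchors_considered"), 1L)

  # overlapping windows: a gene inside two anchors' windows counts twice
  anchor2 <- cds$protein_id[36]
  calls2 <- bind_rows(calls, make_calls(anchor2, "VirB4"))
  w2 <- extract_neighborhoods(cds, c(anchor, anchor2), k = 20)
  pa2 <- positional_abundance(w2, calls2)
  expect_equal(sum(pa2$n[pa2$category == "VirB3"]), 2L)
  # conservation: total counts equal (anchor, called-gene) incidences
  incidences <- nrow(inner_join(w2, calls2[, c("protein_id", "category")],
                                by = "protein_id",
                                relationship = "many-to-many"))
  expect_equal(sum(pa2$n), incidences)
})

test_that("association partitions a category exactly into near and far", {
  cds <- bind_rows(make_cds(60, contig = "c1"),
                   make_cds(10, contig = "c2"))
  anchor <- cds$protein_id[31] # c1 index 30
  near_t4cp <- cds$protein_id[50]  # offset +19
  far_t4cp <- cds$protein_id[cds$contig_id == "c2"][5] # no anchor there
  calls <- bind_rows(make_calls(anchor, "VirB4"),
                     make_calls(c(near_t4cp, far_t4cp), "T4CP"))
  w <- extract_neighborhoods(cds, anchor, k = 20)
  s <- association_summary(calls, w, "T4CP")
  expect_equal(s$n_near, 1L)
  expect_equal(s$n_far, 1L)
  expect_equal(s$n_near + s$n_far, s$n_total)
})

test_that("pair proximity counts distinct neighbours within k ranks", {
  cds <- make_cds(100)
  calls <- bind_rows(
    make_calls(cds$protein_id[c(10, 60)], "Relaxase_MOBC"),
    make_calls(cds$protein_id[c(25, 95)], "T4CP")
  )
  pp <- pair_proximity(cds, calls, "Relaxase_MOBC", "T4CP", k = 20)
  expect_equal(pp$n_a_total, 2L)
  expect_equal(pp$n_a_near_b, 1L) # index 9 vs 24 within 20; 59 is not
  # a protein is never its own neighbour
  both <- bind_rows(make_calls(cds$protein_id[10], "T4CP"), calls)
  pp2 <- pair_proximity(cds, both, "T4CP", "T4CP", k = 20)
  expect_equal(pp2$n_a_near_b, 2L) # indices 9 and 24, mutual; 94 alone
})

test_that("contig-end distances count CDS to the nearer end", {
  cds <- make_cds(100)
  d <- cds_to_contig_end(cds)
  expect_equal(d$dist_to_end[d$index == 0], 0L)
  expect_equal(d$dist_to_end[d$index == 30], 30L)
  expect_equal(d$dist_to_end[d$index == 99], 0L)
})

test_that("context family table ranks by windows hit, ties lexicographic", {
  cds <- make_cds(120)
  anchors <- cds$protein_id[c(31, 91)]
  w <- extract_neighborhoods(cds, anchors, k = 20)
  classes <- tibble(assembly_id = "A1", class_label = "classX")
  fh <- bind_rows(
    make_hit(cds$protein_id[30], "NCBIFAM", "dnaA"),
    make_hit(cds$protein_id[90], "NCBIFAM", "dnaA"),
    make_hit(cds$protein_id[32], "NCBIFAM", "zzz"),
    make_hit(cds$protein_id[33], "NCBIFAM", "aaa")
  )
  tab <- context_family_table(w, fh, classes)
  expect_equal(tab$profile_name[tab$rank == 1], "dnaA")
  expect_equal(tab$n_windows[tab$rank == 1], 2L)
  # tie between aaa and zzz broken lexicographically
  expect_equal(tab$profile_name[tab$rank == 2], "aaa")
  # fewer families than top_n: all returned, no padding
  expect_equal(nrow(tab), 3)
})
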