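test_that("patristic distances sum branch lengths along the path", {
  t <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):2);")
  m <- patristic_matrix(t)
  expect_equal(m["A", "B"], 3)
  expect_equal(m["A", "C"], 5)
  expect_equal(diag(m), setNames(rep(0, 4), t$tip.label))
  t_neg <- t
  t_neg$edge.length[2] <- -0.1
  expect_error(patristic_matrix(t_neg), "negative")
})

test_that("midpoint rooting splits the longest leaf path in half", {
  t <- ape::read.tree(text = "(A:1,(B:1,C:4):1);")
  mt <- midpoint_root(t)
  depths <- ape::node.depth.edgelength(mt)[seq_along(mt$tip.label)]
  names(depths) <- mt$tip.label
  # longest path A-C has length 6: root must be 3 from each extreme
  expect_equal(unname(depths["A"]), 3)
  expect_equal(unname(depths["C"]), 3)

  t2 <- ape::read.tree(text = "(A:1,B:3);")
  d2 <- ape::node.depth.edgelength(midpoint_root(t2))[1:2]
  expect_equal(d2, c(2, 2))

  # idempotence up to the root-edge split: distances unchanged
  m1 <- patristic_matrix(mt)
  m2 <- patristic_matrix(midpoint_root(mt))
  expect_equal(m2[rownames(m1), colnames(m1)], m1)
})

test_that("provenance records report per-leaf minima and classification", {
  t <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):2);")
  labels <- tibble(leaf = c("A", "B", "C", "D"),
                   class_label = c("c1", "c1", "c2", "c2"))
  rec <- provenance_records(patristic_matrix(t), labels)
  a <- rec[rec$leaf == "A", ]
  expect_equal(a$d_same, 3)
  expect_equal(a$d_diff, 5)
  expect_true(a$closest_is_same_class)
  expect_true(all(rec$closest_is_same_class))
  s <- provenance_summary(rec)
  expect_equal(s$pct_same, 100)
  expect_equal(s$n_identical_same_class, 0)
})

test_that("ties classify as same-class and zero distances are flagged", {
  # star-ish tree: d(A,B) = 2 = d(A,C)
  t <- ape::read.tree(text = "(A:1,B:1,C:1);")
  labels <- tibble(leaf = c("A", "B", "C"),
                   class_label = c("c1", "c1", "c2"))
  rec <- provenance_records(patristic_matrix(t), labels)
  expect_true(rec$closest_is_same_class[rec$leaf == "A"])

  tz <- ape::read.tree(text = "((A:0,B:0):1,C:1);")
  recz <- provenance_records(patristic_matrix(tz), labels)
  expect_true(all(recz$has_identical_same_class[recz$leaf %in% c("A", "B")]))
  expect_false(recz$has_identical_same_class[recz$leaf == "C"])
})

test_that("singleton classes are excluded from the classified denominator", {
  t <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  labels <- tibble(leaf = c("A", "B", "C"),
                   class_label = c("c1", "c1", "c9"))
  rec <- provenance_records(patristic_matrix(t), labels)
  expect_true(is.na(rec$d_same[rec$leaf == "C"]))
  s <- provenance_summary(rec)
  expect_equal(s$n_classified, 2)
  expect_equal(s$n_singleton_class, 1)
  expect_equal(s$pct_same + s$pct_diff, 100)
})

test_that("patristic distances satisfy the four-point condition", {
  set.seed(11)
  for (rep in 1:10) {
    t <- ape::rtree(12)
    m <- patristic_matrix(t)
    tips <- rownames(m)
    for (q in 1:20) {
      ijkl <- sample(tips, 4)
      s1 <- m[ijkl[1], ijkl[2]] + m[ijkl[3], ijkl[4]]
      s2 <- m[ijkl[1], ijkl[3]] + m[ijkl[2], ijkl[4]]
      s3 <- m[ijkl[1], ijkl[4]] + m[ijkl[2], ijkl[3]]
      sums <- sort(c(s1, s2, s3))
      expect_equal(sums[2], sums[3], tolerance = 1e-9)
    }
  }
})

test_that("the empirical distance CDF is right-continuous and ends at 1", {
  cdf <- distance_cdf(c(0, 0, 1))
  expect_equal(cdf$distance, c(0, 1))
  expect_equal(cdf$cum_frac, c(2 / 3, 1))
  one <- distance_cdf(rep(2.5, 10))
  expect_equal(nrow(one), 1)
  expect_equal(one$cum_frac, 1)
  expect_error(distance_cdf(numeric(0)), "empty")
  expect_true(all(diff(distance_cdf(runif(50))$cum_frac) > 0))
})

test_that("provenance analysis object supports tidy, glance and autoplot", {
  sim <- simulate_labelled_tree(n_leaves = 40, n_classes = 2,
                                transfer_fraction = 0.1, n_zero_pairs = 1,
                                seed = 5)
  pv <- provenance_analysis(sim$tree, sim$labels)
  expect_s3_class(pv, "t4ss_provenance")
  expect_equal(nrow(tidy(pv)), 40)
  g <- glance(pv)
  expect_equal(g$n_leaves, 40)
  expect_equal(g$n_closest_diff, sum(sim$truth$is_transfer))
  expect_equal(g$n_identical_same_class, 2)
  expect_s3_class(ggplot2::autoplot(pv), "ggplot")
})
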