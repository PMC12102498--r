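#' Patristic distance matrix of a tree
#'
#' Leaf-to-leaf distances summing branch lengths along the unique path
#' (computed with `ape::cophenetic.phylo`, the standard route for gene-tree
#' patristic matrices). Negative branch lengths are an error.
#'
#' @param tree An ape `phylo` with branch lengths.
#' @return Symmetric numeric matrix with leaf labels as dimnames and zero
#'   diagonal.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) rlang::abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) rlang::abort("negative branch length")
  stats::cophenetic(tree)
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path (via
#' `phangorn::midpoint`). Rerooting does not change any patristic distance.
#'
#' @param tree An ape `phylo` with at least 2 leaves.
#' @return The rerooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) rlang::abort("need at least 2 leaves")
  phangorn::midpoint(tree)
}

#' Per-leaf nearest same-class / different-class homologue records
#'
#' For every leaf, the minimal patristic distance to another leaf of the
#' same taxonomic class (`d_same`) and to a leaf of a different class
#' (`d_diff`), the resulting classification
#' `closest_is_same_class = (d_same <= d_diff)` — ties count as same-class,
#' the conservative reading when between-class transfer is the signal of
#' interest — and whether an effectively identical same-class homologue
#' exists (`d_same <= tolerance`). A leaf whose class has no other member
#' gets `d_same = NA` and is excluded from the classification (reported via
#' `NA`); a single-class tree likewise yields `d_diff = NA`.
#'
#' @param dmat Patristic matrix from [patristic_matrix()].
#' @param labels Tibble with `leaf` and `class_label` (one row per leaf),
#'   or a named character vector of class labels.
#' @param tolerance Distance at or below which two homologues count as
#'   identical (default 0, exact).
#' @return Tibble with `leaf`, `class_label`, `d_same`, `d_diff`,
#'   `closest_is_same_class`, `has_identical_same_class`.
#' @export
provenance_records <- function(dmat, labels, tolerance = 0) {
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(leaf = names(labels),
                             class_label = unname(labels))
  }
  check_columns(labels, c("leaf", "class_label"), "`labels`")
  leaves <- rownames(dmat)
  if (!setequal(leaves, labels$leaf)) {
    rlang::abort("`labels` must cover exactly the leaves of the matrix")
  }
  if (anyNA(labels$class_label)) rlang::abort("leaf without a class label")
  cls <- setNames(labels$class_label, labels$leaf)[leaves]
  work <- dmat
  diag(work) <- Inf
  d_same <- d_diff <- rep(NA_real_, length(leaves))
  for (cl in unique(cls)) {
    in_cl <- cls == cl
    if (sum(in_cl) >= 2) {
      d_same[in_cl] <- apply(work[in_cl, in_cl, drop = FALSE], 1, min)
    }
    if (any(!in_cl)) {
      d_diff[in_cl] <- apply(work[in_cl, !in_cl, drop = FALSE], 1, min)
    }
  }
  tibble::tibble(
    leaf = leaves,
    class_label = unname(cls),
    d_same = d_same,
    d_diff = d_diff,
    closest_is_same_class = ifelse(
      is.na(d_same) | is.na(d_diff), NA, d_same <= d_diff),
    has_identical_same_class = !is.na(d_same) & d_same <= tolerance
  )
}

#' Summarise provenance records
#'
#' Fractions of leaves whose closest homologue is in the same vs a
#' different class. Two denominators are reported: leaves with both minima
#' defined (`pct_same`, `pct_diff`) and all leaves
#' (`pct_diff_of_all`), since surveys differ in how they treat leaves
#' from singleton classes.
#'
#' @param records Tibble from [provenance_records()].
#' @return One-row tibble: `n_leaves`, `n_classified`, `n_singleton_class`,
#'   `n_closest_same`, `n_closest_diff`, `pct_same`, `pct_diff`,
#'   `pct_diff_of_all`, `n_identical_same_class`.
#' @export
provenance_summary <- function(records) {
  classified <- dplyr::filter(records, !is.na(.data$closest_is_same_class))
  n_same <- sum(classified$closest_is_same_class)
  n_diff <- sum(!classified$closest_is_same_class)
  tibble::tibble(
    n_leaves = nrow(records),
    n_classified = nrow(classified),
    n_singleton_class = sum(is.na(records$d_same)),
    n_closest_same = n_same,
    n_closest_diff = n_diff,
    pct_same = if (nrow(classified) > 0) {
      round(100 * n_same / nrow(classified), 2)
    } else {
      NA_real_
    },
    pct_diff = if (nrow(classified) > 0) {
      round(100 * n_diff / nrow(classified), 2)
    } else {
      NA_real_
    },
    pct_diff_of_all = round(100 * n_diff / nrow(records), 2),
    n_identical_same_class = sum(records$has_identical_same_class)
  )
}

#' Provenance analysis of a labelled gene tree
#'
#' End-to-end convenience wrapper: midpoint-roots the tree, computes the
#' patristic matrix and returns the per-leaf records and summary as a
#' fitted-object-style result with [tidy()], [glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @param tree An ape `phylo` with branch lengths.
#' @param labels Tibble with `leaf`, `class_label` (see
#'   [provenance_records()]).
#' @param tolerance Identity tolerance on patristic distance (default 0).
#' @return An object of class `t4ss_provenance`: list with `records`,
#'   `summary`, `tolerance`.
#' @export
provenance_analysis <- function(tree, labels, tolerance = 0) {
  tree <- midpoint_root(tree)
  dmat <- patristic_matrix(tree)
  records <- provenance_records(dmat, labels, tolerance = tolerance)
  structure(
    list(records = records, summary = provenance_summary(records),
         tolerance = tolerance),
    class = "t4ss_provenance"
  )
}

#' @export
print.t4ss_provenance <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "T4SS provenance analysis: %d leaves (%d classified)\n", s$n_leaves,
    s$n_classified))
  cat(sprintf(
    "  closest homologue same class: %d (%.2f%%), different class: %d (%.2f%%)\n",
    s$n_closest_same, s$pct_same, s$n_closest_diff, s$pct_diff))
  cat(sprintf("  leaves with an identical same-class homologue: %d\n",
              s$n_identical_same_class))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.t4ss_provenance <- function(x, ...) x$records

#' @export
glance.t4ss_provenance <- function(x, ...) x$summary

#' Empirical CDF of a distance multiset
#'
#' Right-continuous cumulative distribution used to display minimal
#' patristic distances: breakpoints are the sorted distinct values and the
#' final cumulative fraction is 1.
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @return Tibble with `distance` and `cum_frac`.
#' @export
distance_cdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) rlang::abort("empty distance set")
  breaks <- sort(unique(values))
  tibble::tibble(
    distance = breaks,
    cum_frac = stats::ecdf(values)(breaks)
  )
}
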