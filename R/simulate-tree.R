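#' Simulate a class-structured gene tree with planted transfers
#'
#' Builds a labelled VirB4-style gene tree: one coalescent subtree per
#' taxonomic class (height scaled to `branch_scale`), joined by long stems
#' (`stem_length`, per-class), plus two kinds of planted signal with exact
#' ground truth:
#'
#' * **Inter-class transfers.** `round(transfer_fraction * n_leaves)`
#'   leaves are attached inside a *foreign* class's subtree, just above its
#'   root, on a pendant branch (`transplant_pendant * branch_scale`) that
#'   is long relative to the within-class depth but short relative to the
#'   stems. By construction these transplants — and only they — have their
#'   closest homologue in a different class, so the recovered
#'   closest-different-class fraction equals the planted fraction up to
#'   rounding.
#' * **Identical homologues.** `n_zero_pairs` zero-length cherries are
#'   planted on same-class leaves; both members of a pair sit at patristic
#'   distance 0, mirroring identical proteins recovered from different
#'   assemblies.
#'
#' @param n_leaves Total number of leaves (transplants and duplicate
#'   leaves included).
#' @param n_classes Number of classes (each keeps at least 2 resident
#'   leaves).
#' @param transfer_fraction Planted fraction `f` of inter-class transfer
#'   leaves; must be < 1 (and 0 when `n_classes == 1`).
#' @param n_zero_pairs Number of zero-distance same-class pairs to plant.
#' @param stem_length Stem length joining class subtrees (default 50).
#' @param transplant_pendant Pendant length of transplant leaves, in units
#'   of `branch_scale` (default 5).
#' @param branch_scale Height of each class subtree (default 1).
#' @param seed Integer seed.
#' @param path Optional file path; when given the tree is also written as
#'   Newick with `protein|assembly|class` leaf labels.
#' @return List with `tree` (ape `phylo`), `labels` (tibble: `leaf`,
#'   `protein_id`, `assembly_id`, `class_label`) and `truth` (tibble:
#'   `leaf`, `class_label`, `is_transfer`, `is_zero_dup`).
#' @export
simulate_labelled_tree <- function(n_leaves = 200, n_classes = 4,
                                   transfer_fraction = 0,
                                   n_zero_pairs = 0,
                                   stem_length = 50,
                                   transplant_pendant = 5,
                                   branch_scale = 1,
                                   seed = 1L, path = NULL) {
  if (transfer_fraction >= 1 || transfer_fraction < 0) {
    rlang::abort("transfer_fraction must be in [0, 1)")
  }
  if (n_classes < 1) rlang::abort("need at least one class")
  if (n_classes == 1 && transfer_fraction > 0) {
    rlang::abort("transfers need at least two classes")
  }
  set.seed(as.integer(seed))
  n_transfer <- round(transfer_fraction * n_leaves)
  n_resident <- n_leaves - n_transfer - n_zero_pairs
  if (n_resident < 2 * n_classes) {
    rlang::abort("too few resident leaves: need >= 2 per class")
  }
  class_names <- sprintf("class_%02d", seq_len(n_classes))
  counts <- rep(n_resident %/% n_classes, n_classes)
  extra <- n_resident %% n_classes
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L

  leaf_id <- 0L
  next_label <- function(cl) {
    leaf_id <<- leaf_id + 1L
    sprintf("P%05d|ASMT%05d|%s", leaf_id, leaf_id, cl)
  }

  subtrees <- lapply(seq_len(n_classes), function(i) {
    tip_labels <- vapply(seq_len(counts[i]), function(j)
      next_label(class_names[i]), character(1))
    sub <- ape::rcoal(counts[i], tip.label = tip_labels)
    h <- max(ape::node.depth.edgelength(sub))
    if (h > 0) sub$edge.length <- sub$edge.length * (branch_scale / h)
    sub
  })
  if (n_classes == 1) {
    tree <- subtrees[[1]]
  } else {
    parts <- vapply(subtrees, function(s) {
      sub(";$", "", ape::write.tree(s))
    }, character(1))
    tree <- ape::read.tree(text = paste0(
      "(", paste0(parts, ":", stem_length, collapse = ","), ");"))
  }

  truth <- tibble::tibble(leaf = tree$tip.label, is_transfer = FALSE,
                          is_zero_dup = FALSE)

  # zero-distance cherries on resident leaves
  if (n_zero_pairs > 0) {
    hosts <- sample(tree$tip.label, n_zero_pairs)
    for (h in hosts) {
      cl <- strsplit(h, "|", fixed = TRUE)[[1]][3]
      lab <- next_label(cl)
      tree <- phytools::bind.tip(tree, lab, edge.length = 0,
                                 where = which(tree$tip.label == h),
                                 position = 0)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        leaf = lab, is_transfer = FALSE, is_zero_dup = TRUE))
      truth$is_zero_dup[truth$leaf == h] <- TRUE
    }
  }

  # transplants: attached just above the host class's subtree root
  if (n_transfer > 0) {
    attach_frac <- 0.1 * stem_length
    for (j in seq_len(n_transfer)) {
      donor <- sample(class_names, 1)
      host <- sample(setdiff(class_names, donor), 1)
      host_tips <- which(grepl(paste0("\\|", host, "$"), tree$tip.label) &
                           !(tree$tip.label %in%
                               truth$leaf[truth$is_transfer]))
      mrca <- ape::getMRCA(tree, host_tips)
      lab <- next_label(donor)
      attach_frac <- attach_frac * 0.7
      tree <- phytools::bind.tip(
        tree, lab, edge.length = transplant_pendant * branch_scale,
        where = mrca, position = attach_frac)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        leaf = lab, is_transfer = TRUE, is_zero_dup = FALSE))
    }
  }

  labels <- parse_leaf_labels(tree$tip.label)
  truth <- dplyr::left_join(
    truth, dplyr::select(labels, "leaf", "class_label"), by = "leaf")
  if (!is.null(path)) ape::write.tree(tree, file = path)
  list(tree = tree, labels = labels, truth = truth)
}
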