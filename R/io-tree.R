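#' Read a labelled VirB4 gene tree from Newick
#'
#' Reads a Newick tree (via ape) whose leaf labels encode the protein id,
#' assembly id and taxonomic class, by default as
#' `proteinid|assemblyid|classlabel`. Missing branch lengths are set to 0
#' with a warning; an unparseable leaf label is an error naming the leaf.
#'
#' @param path Path to a Newick file.
#' @param delim Field delimiter inside leaf labels (default `"|"`).
#' @param fields Names of the delimited label fields, in order. Must
#'   contain `"protein_id"` and `"class_label"`.
#' @return A list with `tree` (an ape `phylo`) and `labels` (tibble with
#'   one row per leaf: `leaf`, plus one column per label field).
#' @export
read_virb4_tree <- function(path, delim = "|",
                            fields = c("protein_id", "assembly_id",
                                       "class_label")) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) rlang::abort(sprintf("could not parse Newick in %s", path))
  if (is.null(tree$edge.length)) {
    rlang::warn("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    rlang::warn(sprintf("%d missing branch length(s) treated as 0",
                        sum(is.na(tree$edge.length))))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  labels <- parse_leaf_labels(tree$tip.label, delim = delim, fields = fields)
  list(tree = tree, labels = labels)
}

#' Parse structured leaf labels into a tibble
#'
#' @param leaves Character vector of leaf labels.
#' @param delim Field delimiter (default `"|"`).
#' @param fields Names for the delimited fields.
#' @return Tibble with column `leaf` plus one column per field.
#' @export
parse_leaf_labels <- function(leaves, delim = "|",
                              fields = c("protein_id", "assembly_id",
                                         "class_label")) {
  parts <- strsplit(leaves, delim, fixed = TRUE)
  bad <- which(lengths(parts) != length(fields))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "leaf label '%s' does not match the %d-field '%s'-delimited scheme",
      leaves[bad[1]], length(fields), delim))
  }
  out <- tibble::tibble(leaf = leaves)
  for (i in seq_along(fields)) {
    out[[fields[i]]] <- vapply(parts, `[`, character(1), i)
  }
  out
}
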