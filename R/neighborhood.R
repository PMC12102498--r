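#' Extract ±k CDS windows around anchor genes
#'
#' For each anchor protein, collects the CDS at rank offsets −k..+k on the
#' same contig (20 upstream and 20 downstream by default). Offsets are
#' CDS-rank differences — intervening non-coding features are invisible and
#' strand is ignored. Windows never cross a contig boundary: near a contig
#' end the window simply contains fewer than k CDS on that side (see
#' [anchor_truncation()] for the truncation report).
#'
#' @param cds CDS tibble (see [read_genome_annotation()]).
#' @param anchors Character vector of anchor protein ids, or a tibble with
#'   a `protein_id` column (e.g. VirB4 calls).
#' @param k Window radius in CDS ranks (default 20).
#' @return Long tibble with one row per (anchor, window member):
#'   `anchor_protein`, `assembly_id`, `contig_id`, `offset`, `protein_id`,
#'   `index`. Offset 0 is the anchor itself.
#' @export
extract_neighborhoods <- function(cds, anchors, k = 20) {
  if (is.data.frame(anchors)) anchors <- anchors$protein_id
  anchors <- unique(anchors)
  check_columns(cds, c("assembly_id", "contig_id", "protein_id", "index"),
                "`cds`")
  placed <- dplyr::filter(cds, !is.na(.data$contig_id), !is.na(.data$index))
  anchor_rows <- placed |>
    dplyr::filter(.data$protein_id %in% anchors) |>
    dplyr::select(anchor_protein = "protein_id", "assembly_id", "contig_id",
                  anchor_index = "index")
  missing <- setdiff(anchors, anchor_rows$anchor_protein)
  if (length(missing) > 0) {
    rlang::abort(sprintf("anchor protein(s) not found on any contig: %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  anchor_rows |>
    dplyr::inner_join(
      dplyr::select(placed, "assembly_id", "contig_id", "protein_id",
                    "index"),
      by = c("assembly_id", "contig_id"),
      relationship = "many-to-many"
    ) |>
    dplyr::mutate(offset = .data$index - .data$anchor_index) |>
    dplyr::filter(abs(.data$offset) <= k) |>
    dplyr::arrange(.data$anchor_protein, .data$offset) |>
    dplyr::select("anchor_protein", "assembly_id", "contig_id", "offset",
                  "protein_id", "index")
}

#' Per-anchor window truncation and contig-end distance
#'
#' Reports, for each anchor, the number of CDS strictly between it and the
#' nearer contig end (`dist_to_end = min(index, n_cds - 1 - index)`), the
#' offsets at which the ±k window is cut by the contig boundary, and the
#' `near_end` flag (`dist_to_end < k`) — i.e. the anchors whose window is
#' truncated and might be missing associated components in a draft
#' assembly.
#'
#' @inheritParams extract_neighborhoods
#' @return Tibble with `anchor_protein`, `assembly_id`, `contig_id`,
#'   `index`, `n_cds`, `dist_to_end`, `upstream_truncated_at`,
#'   `downstream_truncated_at`, `near_end`.
#' @export
anchor_truncation <- function(cds, anchors, k = 20) {
  if (is.data.frame(anchors)) anchors <- anchors$protein_id
  placed <- dplyr::filter(cds, !is.na(.data$contig_id), !is.na(.data$index))
  sizes <- placed |>
    dplyr::count(.data$assembly_id, .data$contig_id, name = "n_cds")
  out <- placed |>
    dplyr::filter(.data$protein_id %in% anchors) |>
    dplyr::left_join(sizes, by = c("assembly_id", "contig_id")) |>
    dplyr::mutate(
      dist_to_end = pmin(.data$index, .data$n_cds - 1L - .data$index),
      upstream_truncated_at = ifelse(.data$index < k, -.data$index,
                                     NA_integer_),
      downstream_truncated_at = ifelse(.data$n_cds - 1L - .data$index < k,
                                       .data$n_cds - 1L - .data$index,
                                       NA_integer_),
      near_end = .data$dist_to_end < k
    ) |>
    dplyr::select(anchor_protein = "protein_id", "assembly_id", "contig_id",
                  "index", "n_cds", "dist_to_end", "upstream_truncated_at",
                  "downstream_truncated_at", "near_end")
  missing <- setdiff(unique(anchors), out$anchor_protein)
  if (length(missing) > 0) {
    rlang::abort(sprintf("anchor protein(s) not found on any contig: %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  out
}

#' Distance from every CDS to the nearer contig end
#'
#' @param cds CDS tibble.
#' @return The placed rows of `cds` with a `dist_to_end` column: the number
#'   of CDS strictly between the gene and the nearer end of its contig.
#' @export
cds_to_contig_end <- function(cds) {
  placed <- dplyr::filter(cds, !is.na(.data$contig_id), !is.na(.data$index))
  placed |>
    dplyr::group_by(.data$assembly_id, .data$contig_id) |>
    dplyr::mutate(dist_to_end = pmin(.data$index, dplyr::n() - 1L -
                                       .data$index)) |>
    dplyr::ungroup()
}

#' Keep anchors associated with another T4SS component
#'
#' Retains the windows whose non-anchor members (offset ≠ 0) include at
#' least one protein called in a T4SS component category other than the
#' anchor's own category — e.g. a virB4 gene is kept only when a second,
#' different T4SS component lies within the window. A second VirB4 copy
#' does not count as a companion, and `Other` calls never do.
#'
#' @param windows Window tibble from [extract_neighborhoods()].
#' @param calls Component call tibble from [assign_components()].
#' @param anchor_category Category of the anchor gene (default `"VirB4"`).
#' @return The subset of `windows` belonging to retained anchors.
#' @export
anchors_with_companion <- function(windows, calls,
                                   anchor_category = "VirB4") {
  companion_calls <- dplyr::filter(
    calls, !.data$category %in% c(anchor_category, "Other"))
  kept <- windows |>
    dplyr::filter(.data$offset != 0) |>
    dplyr::semi_join(companion_calls, by = "protein_id") |>
    dplyr::distinct(.data$anchor_protein)
  dplyr::semi_join(windows, kept, by = "anchor_protein")
}

#' Positional abundance of components relative to the anchor
#'
#' Counts, at every rank offset −k..+k, how many window members carry each
#' component category. Counting is per anchor: a gene lying in two anchors'
#' windows contributes to both columns, and a protein with calls in two
#' categories contributes once per category. Per-offset percentages use the
#' offset's total as 100%.
#'
#' @inheritParams anchors_with_companion
#' @param k Window radius (used only to complete absent offsets).
#' @return Tibble with `offset`, `category`, `n`, `offset_total`, `pct`,
#'   carrying the number of anchors considered in the
#'   `anchors_considered` attribute.
#' @export
positional_abundance <- function(windows, calls, k = 20) {
  pa <- windows |>
    dplyr::inner_join(dplyr::select(calls, "protein_id", "category"),
                      by = "protein_id", relationship = "many-to-many") |>
    dplyr::count(.data$offset, .data$category, name = "n") |>
    dplyr::group_by(.data$offset) |>
    dplyr::mutate(offset_total = sum(.data$n),
                  pct = round(100 * .data$n / .data$offset_total, 1)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$offset, .data$category)
  attr(pa, "anchors_considered") <- dplyr::n_distinct(windows$anchor_protein)
  pa
}

#' Near/far association of a component category with the anchor
#'
#' Partitions all proteins called in `category` into those found inside
#' some anchor window (at offset ≠ 0, i.e. within k CDS of an anchor) and
#' those that are not. The two counts always sum to the category total.
#'
#' @inheritParams anchors_with_companion
#' @param category Component category to summarise (e.g. `"T4CP"`).
#' @return One-row tibble: `category`, `n_near`, `n_far`, `n_total`,
#'   `pct_near`.
#' @export
association_summary <- function(calls, windows, category) {
  members <- dplyr::filter(windows, .data$offset != 0)
  cat_calls <- calls |>
    dplyr::filter(.data$category == !!category) |>
    dplyr::distinct(.data$protein_id)
  near <- dplyr::semi_join(cat_calls, members, by = "protein_id")
  tibble::tibble(
    category = category,
    n_near = nrow(near),
    n_far = nrow(cat_calls) - nrow(near),
    n_total = nrow(cat_calls),
    pct_near = if (nrow(cat_calls) > 0) {
      count_percentage(nrow(near), nrow(cat_calls))
    } else {
      NA_real_
    }
  )
}

#' Proximity of one component category to another
#'
#' Counts the `category_a` genes lying within `k` CDS ranks of a (distinct)
#' `category_b` gene on the same contig — e.g. relaxase genes close to the
#' coupling-protein gene.
#'
#' @param cds CDS tibble.
#' @param calls Component call tibble.
#' @param category_a,category_b Category names.
#' @param k Maximum CDS-rank distance (default 20).
#' @return One-row tibble: `category_a`, `category_b`, `n_a_total`,
#'   `n_a_near_b`.
#' @export
pair_proximity <- function(cds, calls, category_a, category_b, k = 20) {
  placed <- dplyr::filter(cds, !is.na(.data$contig_id), !is.na(.data$index))
  pos_of <- function(cat) {
    calls |>
      dplyr::filter(.data$category == cat) |>
      dplyr::distinct(.data$protein_id) |>
      dplyr::inner_join(dplyr::select(placed, "assembly_id", "contig_id",
                                      "protein_id", "index"),
                        by = "protein_id")
  }
  a <- pos_of(category_a)
  b <- pos_of(category_b)
  near <- a |>
    dplyr::inner_join(b, by = c("assembly_id", "contig_id"),
                      suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$protein_id_a != .data$protein_id_b,
                  abs(.data$index_a - .data$index_b) <= k) |>
    dplyr::distinct(.data$protein_id_a)
  tibble::tibble(category_a = category_a, category_b = category_b,
                 n_a_total = nrow(a), n_a_near_b = nrow(near))
}

#' Most prevalent functional families in anchor neighbourhoods
#'
#' For each taxonomic class and each functional profile database (Pfam,
#' NCBIFAM, TIGRFAM, ...), ranks protein families by the number of anchor
#' windows containing at least one member, and keeps the `top_n` (ties
#' broken lexicographically by family name). Families hitting the anchor
#' itself (offset 0) count: the question is what functions sit in the
#' anchor's chromosomal context.
#'
#' @param windows Window tibble from [extract_neighborhoods()].
#' @param functional_hits Filtered functional-family hit tibble (same
#'   schema as [read_domtblout()] output, after [filter_hits()]).
#' @param classes Tibble mapping `assembly_id` to `class_label`.
#' @param top_n Families to keep per (class, database) (default 6). When
#'   fewer families are present, all are returned without padding.
#' @return Tibble with `class_label`, `profile_set`, `profile_name`,
#'   `n_windows`, `rank`.
#' @export
context_family_table <- function(windows, functional_hits, classes,
                                 top_n = 6) {
  check_columns(classes, c("assembly_id", "class_label"), "`classes`")
  windows |>
    dplyr::inner_join(
      dplyr::select(functional_hits, "protein_id", "profile_set",
                    "profile_name"),
      by = "protein_id", relationship = "many-to-many") |>
    dplyr::left_join(classes, by = "assembly_id") |>
    dplyr::distinct(.data$class_label, .data$profile_set,
                    .data$profile_name, .data$anchor_protein) |>
    dplyr::count(.data$class_label, .data$profile_set, .data$profile_name,
                 name = "n_windows") |>
    dplyr::group_by(.data$class_label, .data$profile_set) |>
    dplyr::arrange(dplyr::desc(.data$n_windows), .data$profile_name,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
}
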