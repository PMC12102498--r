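#' Detect tandem pilin (VirB2) arrays
#'
#' Finds maximal runs of VirB2-called CDS on each contig in which
#' consecutive pilin genes are adjacent or separated by at most
#' `max_spacer` non-pilin CDS (default 1: "in tandem or separated by a
#' non-pilin gene"). Runs with at least `min_size` pilins are reported;
#' two pilins separated by two or more non-pilin genes never join the same
#' array, and arrays never span contigs.
#'
#' @param cds CDS tibble (see [read_genome_annotation()]).
#' @param calls Component call tibble; rows with `category == pilin_category`
#'   define the pilin gene set.
#' @param max_spacer Maximum number of intervening non-pilin CDS between
#'   consecutive members (default 1).
#' @param min_size Minimum number of pilin genes per reported array
#'   (default 2).
#' @param pilin_category Category treated as pilin (default `"VirB2"`).
#' @return Tibble with one row per array: `assembly_id`, `contig_id`,
#'   `array_id`, `n_pilins`, `member_ids` (list of protein ids in contig
#'   order), `member_indices` (list), `spacer_positions` (list of CDS ranks
#'   of single intervening non-pilin genes), `n_spacers`.
#' @export
detect_arrays <- function(cds, calls, max_spacer = 1, min_size = 2,
                          pilin_category = "VirB2") {
  pilins <- calls |>
    dplyr::filter(.data$category == pilin_category) |>
    dplyr::distinct(.data$protein_id)
  placed <- cds |>
    dplyr::filter(!is.na(.data$contig_id), !is.na(.data$index)) |>
    dplyr::semi_join(pilins, by = "protein_id") |>
    dplyr::arrange(.data$assembly_id, .data$contig_id, .data$index)
  if (nrow(placed) == 0) {
    return(tibble::tibble(
      assembly_id = character(), contig_id = character(),
      array_id = character(), n_pilins = integer(),
      member_ids = list(), member_indices = list(),
      spacer_positions = list(), n_spacers = integer()
    ))
  }
  placed |>
    dplyr::group_by(.data$assembly_id, .data$contig_id) |>
    dplyr::mutate(
      run = cumsum(c(0L, diff(.data$index) > max_spacer + 1L))
    ) |>
    dplyr::group_by(.data$assembly_id, .data$contig_id, .data$run) |>
    dplyr::summarise(
      n_pilins = dplyr::n(),
      member_ids = list(.data$protein_id),
      member_indices = list(.data$index),
      spacer_positions = list({
        idx <- .data$index
        gaps <- which(diff(idx) == 2L)
        if (length(gaps) > 0) idx[gaps] + 1L else integer(0)
      }),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pilins >= min_size) |>
    dplyr::mutate(
      n_spacers = lengths(.data$spacer_positions),
      array_id = sprintf("%s:%s:%d", .data$assembly_id, .data$contig_id,
                         purrr::map_int(.data$member_indices, 1))
    ) |>
    dplyr::select("assembly_id", "contig_id", "array_id", "n_pilins",
                  "member_ids", "member_indices", "spacer_positions",
                  "n_spacers")
}

#' Pairwise identity statistics of pilin arrays
#'
#' For each array, the mean and maximum percent amino-acid identity over
#' all `n_pilins * (n_pilins - 1) / 2` member pairs (global alignment, see
#' [pairwise_identity()]). A member without a sequence is an error.
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @param seqs Tibble with `protein_id`, `aa_seq`, or a named character
#'   vector of sequences.
#' @return `arrays` with `mean_pct_id` and `max_pct_id` columns added.
#' @export
array_identity_stats <- function(arrays, seqs) {
  if (is.data.frame(seqs)) {
    check_columns(seqs, c("protein_id", "aa_seq"), "`seqs`")
    seqs <- setNames(seqs$aa_seq, seqs$protein_id)
  }
  stats <- purrr::map(arrays$member_ids, function(ids) {
    s <- seqs[ids]
    if (anyNA(s) || length(s) < length(ids)) {
      rlang::abort(sprintf(
        "missing sequence for array member(s): %s",
        paste(ids[is.na(s) | !(ids %in% names(seqs))], collapse = ", ")))
    }
    pairs <- utils::combn(length(s), 2)
    ids_pct <- apply(pairs, 2, function(p) pairwise_identity(s[p[1]], s[p[2]]))
    c(mean = mean(ids_pct), max = max(ids_pct))
  })
  arrays |>
    dplyr::mutate(
      mean_pct_id = purrr::map_dbl(stats, "mean"),
      max_pct_id = purrr::map_dbl(stats, "max")
    )
}
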