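#' Genome quality score (completeness − 5 × contamination)
#'
#' The draft-genome inclusion score used by GTDB: completeness minus five
#' times contamination, both in percent. May be negative.
#'
#' @param completeness CheckM-style completeness estimate, percent in
#'   \[0, 100\] (vectorised).
#' @param contamination Contamination estimate, percent in \[0, 100\].
#' @return Numeric vector of quality scores.
#' @examples
#' quality_score(90, 5) # 65
#' @export
quality_score <- function(completeness, contamination) {
  if (any(is.na(completeness)) || any(is.na(contamination))) {
    rlang::abort("missing QC estimate")
  }
  if (any(completeness < 0 | completeness > 100) ||
      any(contamination < 0 | contamination > 100)) {
    rlang::abort("completeness and contamination must be percentages in [0, 100]")
  }
  completeness - 5 * contamination
}

#' Genome quality gate
#'
#' A genome passes when completeness > 50, contamination < 10 and
#' quality score > 50 — all three strict, exactly the draft-quality
#' inclusion gate applied to the assemblies. Note a genome can reach a
#' score above 50 yet fail on the contamination bound alone.
#'
#' @inheritParams quality_score
#' @return Logical vector.
#' @examples
#' passes_quality_gate(51, 0)  # TRUE
#' passes_quality_gate(50, 0)  # FALSE: completeness not > 50
#' passes_quality_gate(80, 6)  # FALSE: score exactly 50 is not > 50
#' @export
passes_quality_gate <- function(completeness, contamination) {
  score <- quality_score(completeness, contamination)
  completeness > 50 & contamination < 10 & score > 50
}

#' Apply the quality gate to an assembly table
#'
#' @param qc Tibble with `assembly_id`, `completeness`, `contamination`
#'   (e.g. from [read_taxonomy_qc()]).
#' @return The input with `quality_score` and `passes` columns added.
#' @export
qc_gate <- function(qc) {
  check_columns(qc, c("assembly_id", "completeness", "contamination"), "`qc`")
  dplyr::mutate(
    tibble::as_tibble(qc),
    quality_score = quality_score(.data$completeness, .data$contamination),
    passes = passes_quality_gate(.data$completeness, .data$contamination)
  )
}
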