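#' Profile coverage of a domain alignment
#'
#' Fraction of the HMM profile spanned by the reported domain alignment:
#' `(hmm_to - hmm_from + 1) / profile_length`. Coverage is computed on
#' profile (HMM) coordinates, not on the target protein.
#'
#' @param hmm_from,hmm_to 1-based inclusive alignment coordinates on the
#'   profile (vectorised).
#' @param profile_length Profile length in match states.
#' @return Numeric vector of coverage fractions in (0, 1\].
#' @examples
#' profile_coverage(26, 75, 100) # 0.5 — fails a strict > 0.5 cut
#' @export
profile_coverage <- function(hmm_from, hmm_to, profile_length) {
  if (any(hmm_from < 1 | hmm_from > hmm_to | hmm_to > profile_length)) {
    rlang::abort("need 1 <= hmm_from <= hmm_to <= profile_length")
  }
  (hmm_to - hmm_from + 1) / profile_length
}

#' Filter profile hits on i-Evalue and profile coverage
#'
#' Keeps domains with per-domain independent E-value strictly below
#' `max_i_evalue` and profile coverage strictly above
#' `min_profile_coverage` (the survey's inclusion criteria: i-Evalue
#' < 0.001 and coverage > 50%). Domains are judged individually — multiple
#' domains of one protein against one profile are not merged; a protein is
#' retained if any of its domains passes. Input row order is preserved.
#'
#' @param hits Hit tibble (see [read_domtblout()]).
#' @param max_i_evalue Strict upper bound on the i-Evalue (default 0.001).
#' @param min_profile_coverage Strict lower bound on profile coverage
#'   (default 0.5; must be in (0, 1\]).
#' @return The passing subset of `hits`, with a `coverage` column added.
#' @export
filter_hits <- function(hits, max_i_evalue = 0.001,
                        min_profile_coverage = 0.5) {
  stopifnot(min_profile_coverage > 0, min_profile_coverage <= 1)
  check_columns(hits, c("i_evalue", "hmm_from", "hmm_to", "profile_length"),
                "`hits`")
  hits <- tibble::as_tibble(hits)
  hits$coverage <- profile_coverage(hits$hmm_from, hits$hmm_to,
                                    hits$profile_length)
  dplyr::filter(hits,
                .data$i_evalue < max_i_evalue,
                .data$coverage > min_profile_coverage)
}

#' Profile-to-component mapping table
#'
#' The shipped mapping from (profile set, profile name) to T4SS component
#' category, mirroring the published legend: e.g. VirB1 comprises MPF_FATA
#' TrsG and CD419 and MPF_T VirB1; VirB2 includes MPF_B TraE, MPF_G
#' Tfc9/Tfc10, MPF_I TraQ/TraR, MPF_T VirB2 and Pfam PF04956.16/PF18895.3.
#' The same profile name maps differently in different sets (TraE of MPF_B
#' is VirB2; TraE of MPF_F is VirB8), which is why the set is part of the
#' key. Relaxase profiles (MOB classes) enter through the same mechanism.
#'
#' @return Tibble with `profile_set`, `profile_name`, `category`.
#' @export
component_mapping <- function() {
  path <- system.file("extdata", "component_profile_map.tsv",
                      package = "anchorscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' T4SS component categories
#'
#' All component categories the mapping table can assign, excluding the
#' fallback `Other`.
#'
#' @return Character vector of category names.
#' @export
t4ss_categories <- function() {
  unique(component_mapping()$category)
}

#' Resolve filtered hits into component calls
#'
#' Maps each hit to its component category through the
#' (profile set, profile name) mapping and collapses to one call per
#' (protein, category): among the hits mapping to a category, the
#' highest-scoring one provides the source profile (ties broken by profile
#' set then name, for determinism). A protein may legitimately carry calls
#' in several categories. Hits whose profile is absent from the mapping are
#' called `Other`, and their number is reported in one warning.
#'
#' @param hits Filtered hit tibble (see [filter_hits()]).
#' @param mapping Mapping tibble with `profile_set`, `profile_name`,
#'   `category`; defaults to the shipped [component_mapping()].
#' @return Tibble with `protein_id`, `category`, `profile_set`,
#'   `profile_name`, `bitscore` plus `i_evalue`/`coverage` when present.
#' @export
assign_components <- function(hits, mapping = component_mapping()) {
  check_columns(hits, c("protein_id", "profile_set", "profile_name",
                        "bitscore"), "`hits`")
  check_columns(mapping, c("profile_set", "profile_name", "category"),
                "`mapping`")
  calls <- dplyr::left_join(tibble::as_tibble(hits), mapping,
                            by = c("profile_set", "profile_name"))
  n_unmapped <- sum(is.na(calls$category))
  if (n_unmapped > 0) {
    rlang::warn(sprintf(
      "%d hit(s) against profiles absent from the mapping were called 'Other'",
      n_unmapped))
    calls$category[is.na(calls$category)] <- "Other"
  }
  calls |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$profile_set,
                   .data$profile_name) |>
    dplyr::distinct(.data$protein_id, .data$category, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("protein_id", "category", "profile_set",
                                  "profile_name", "bitscore", "i_evalue",
                                  "coverage")))
}
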