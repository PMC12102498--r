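#' Read an HMMER3 per-domain tabular file (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmscan --domtblout` (target = profile, query = protein). One row is
#' returned per domain: a protein with two reported domains against the
#' same profile yields two rows, and each domain is filtered on its own
#' merits downstream (per-domain independent E-value semantics).
#'
#' Column mapping: `profile_name` = target name, `profile_length` = tlen,
#' `protein_id` = query name, `i_evalue` = the per-domain independent
#' E-value column, `bitscore` = the per-domain score, `hmm_from`/`hmm_to` =
#' the alignment coordinates on the profile.
#'
#' @param path Path to a domtblout file (`#` comment lines are skipped).
#' @param profile_set_label Label recorded in `profile_set` for every row,
#'   e.g. `"MPF_FATA"` or `"Pfam"`. The same profile name can map to
#'   different components in different sets, so the set label is part of
#'   the hit's identity.
#' @return Tibble with columns `protein_id`, `profile_set`, `profile_name`,
#'   `profile_length`, `i_evalue`, `bitscore`, `hmm_from`, `hmm_to`.
#' @export
read_domtblout <- function(path, profile_set_label) {
  stopifnot(is.character(profile_set_label), length(profile_set_label) == 1)
  lines <- readr::read_lines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body_idx) == 0) {
    return(tibble::tibble(
      protein_id = character(), profile_set = character(),
      profile_name = character(), profile_length = integer(),
      i_evalue = double(), bitscore = double(),
      hmm_from = integer(), hmm_to = integer()
    ))
  }
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  parse_row <- function(f, lineno) {
    if (length(f) < 22) {
      rlang::abort(sprintf(
        "malformed domtblout row at line %d: expected >= 22 fields, got %d",
        lineno, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(3, 13, 14, 16, 17)]))
    if (anyNA(num)) {
      rlang::abort(sprintf(
        "malformed domtblout row at line %d: non-numeric field", lineno))
    }
    list(profile_name = f[1], profile_length = as.integer(num[1]),
         protein_id = f[4], i_evalue = num[2], bitscore = num[3],
         hmm_from = as.integer(num[4]), hmm_to = as.integer(num[5]))
  }
  rows <- purrr::map2(fields, body_idx, parse_row)
  hits <- tibble::tibble(
    protein_id = purrr::map_chr(rows, "protein_id"),
    profile_set = profile_set_label,
    profile_name = purrr::map_chr(rows, "profile_name"),
    profile_length = purrr::map_int(rows, "profile_length"),
    i_evalue = purrr::map_dbl(rows, "i_evalue"),
    bitscore = purrr::map_dbl(rows, "bitscore"),
    hmm_from = purrr::map_int(rows, "hmm_from"),
    hmm_to = purrr::map_int(rows, "hmm_to")
  )
  bad <- which(!(hits$hmm_from >= 1 & hits$hmm_from <= hits$hmm_to &
                   hits$hmm_to <= hits$profile_length))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid profile coordinates at line %d: need 1 <= hmm_from <= hmm_to <= profile_length",
      body_idx[bad[1]]))
  }
  hits
}

#' Write profile hits as an HMMER3 domtblout file
#'
#' Inverse of [read_domtblout()], used by the synthetic-data generator.
#' Fields not represented in the hit table (sequence E-value, bias,
#' alignment/envelope coordinates on the protein) are written as
#' placeholders consistent with the format.
#'
#' @param hits Tibble of profile hits (see [read_domtblout()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  check_columns(hits, c("protein_id", "profile_name", "profile_length",
                        "i_evalue", "bitscore", "hmm_from", "hmm_to"),
                "`hits`")
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  qlen <- pmax(hits$hmm_to - hits$hmm_from + 1L, 1L)
  rows <- sprintf(
    "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 %d %d 1 %d 1 %d 0.99 -",
    hits$profile_name, hits$profile_length, hits$protein_id, qlen,
    hits$i_evalue, hits$bitscore, hits$i_evalue, hits$i_evalue,
    hits$bitscore, hits$hmm_from, hits$hmm_to, qlen, qlen
  )
  readr::write_lines(c(header, rows, "#"), path)
  invisible(path)
}
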