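#' Percentage of a count, rounded for reporting
#'
#' Report-style percentage `100 * x / n`, rounded to a fixed number of
#' decimals (one by default, the convention used throughout the package's
#' summary tables).
#'
#' @param x Numerator count (vectorised).
#' @param n Denominator count.
#' @param digits Decimals to keep.
#' @return Numeric vector of percentages.
#' @examples
#' count_percentage(129, 2474) # 5.2
#' @export
count_percentage <- function(x, n, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(n))
  if (any(n <= 0)) rlang::abort("`n` must be positive")
  round(100 * x / n, digits)
}

# internal: check a data frame has the named columns
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# internal: deterministic 32-bit sub-seed stream
derive_subseed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index) %% 2147483647)
}
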