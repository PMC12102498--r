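#' Plot positional abundance of components around the anchor
#'
#' Stacked bars of component counts at each CDS offset relative to the
#' anchor gene, the classic anchored-synteny summary.
#'
#' @param pa Tibble from [positional_abundance()].
#' @param drop_anchor Drop the offset-0 column (the anchor itself)?
#'   Default TRUE.
#' @return A ggplot object.
#' @export
plot_positional_abundance <- function(pa, drop_anchor = TRUE) {
  if (drop_anchor) pa <- dplyr::filter(pa, .data$offset != 0)
  ggplot2::ggplot(pa, ggplot2::aes(x = .data$offset, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::labs(x = "CDS offset from anchor", y = "component count",
                  fill = "component") +
    ggplot2::theme_minimal()
}

#' Plot the CDFs of minimal same-class and different-class distances
#'
#' Step curves of the empirical cumulative distribution of each leaf's
#' minimal patristic distance to its closest same-class and
#' different-class homologue.
#'
#' @param records Tibble from [provenance_records()].
#' @return A ggplot object.
#' @export
plot_distance_cdf <- function(records) {
  curves <- dplyr::bind_rows(
    dplyr::mutate(distance_cdf(records$d_same), which = "same class"),
    if (any(!is.na(records$d_diff))) {
      dplyr::mutate(distance_cdf(records$d_diff), which = "different class")
    }
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$distance,
                                       y = .data$cum_frac,
                                       colour = .data$which)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "minimal patristic distance",
                  y = "cumulative fraction of leaves", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_distance_cdf
#' @param object A `t4ss_provenance` object from [provenance_analysis()].
#' @param ... Ignored.
#' @export
autoplot.t4ss_provenance <- function(object, ...) {
  plot_distance_cdf(object$records)
}

#' Plot the pilin-array size distribution
#'
#' @param arrays Tibble from [detect_arrays()].
#' @return A ggplot object.
#' @export
plot_array_sizes <- function(arrays) {
  ggplot2::ggplot(arrays, ggplot2::aes(x = factor(.data$n_pilins))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "pilin genes per array", y = "arrays") +
    ggplot2::theme_minimal()
}
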