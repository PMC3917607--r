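# ggplot2 views of the per-position tracks, the detector function and the
# genotype feature space.

#' Plot position profiles
#'
#' Facets the trimmed depth, normalized depth and normalized gated mismatch
#' tracks along the reference.
#'
#' @param object An `indel_profiles` tibble (normalized).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot indel_profiles
#' @export
autoplot.indel_profiles <- function(object, ...) {
  cols <- intersect(c("depth", "d_hat", "m1_hat"), names(object))
  long <- tidyr::pivot_longer(as_tibble(object)[, c("pos", cols)],
                              -"pos", names_to = "track")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::labs(x = "reference position (bp)", y = NULL)
}

#' Plot the indel detector function
#'
#' @param object A `detector_track`.
#' @param candidates Optional [select_candidates()] output to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detector_track
#' @export
autoplot.detector_track <- function(object, candidates = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$pos, y = .data$f)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "reference position (bp)", y = "indel detector f(k)")
  if (!is.null(candidates) && nrow(candidates)) {
    p <- p + ggplot2::geom_point(data = as_tibble(candidates),
                                 colour = "red", size = 0.8)
  }
  p
}

#' Scatter of indel features by spike fraction or zygosity
#'
#' The classic view of the genotype feature space: normalized mismatch peak
#' against normalized depth, coloured by class.
#'
#' @param features Feature tibble with `d_hat`, `m1_hat` and a grouping
#'   column (`fraction` or `zygosity`).
#' @param colour Name of the grouping column (default auto-detected).
#' @return A ggplot.
#' @export
plot_indel_features <- function(features, colour = NULL) {
  colour <- colour %||% intersect(c("zygosity", "fraction"), names(features))[1]
  if (is.na(colour)) abort("no zygosity or fraction column to colour by")
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$m1_hat, y = .data$d_hat,
                               colour = factor(.data[[colour]]))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "normalized mismatch peak", y = "normalized depth",
                  colour = colour)
}
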