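#' Plot a TRE-versus-coverage curve
#'
#' Line plot of TRE against surface coverage with the best (minimal-TRE)
#' point highlighted in red, one panel per viewpoint when the curve carries
#' `viewpoint`/`mode` columns.
#'
#' @param object A `coverage_curve` (possibly row-bound with `viewpoint` and
#'   `mode` columns, as in an experiment report).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$coverage, y = .data$tre)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$best),
                        colour = "red", size = 2.5) +
    ggplot2::labs(x = "surface coverage (fraction of vertices)",
                  y = "TRE (mm)") +
    ggplot2::theme_minimal()
  if (all(c("viewpoint", "mode") %in% names(object)))
    p <- p + ggplot2::facet_grid(mode ~ viewpoint)
  p
}

#' Plot a completion-error distance map
#'
#' Scatter of the generated-target vertices coloured by their distance to
#' the ground truth (a flat stand-in for the usual colour-mapped 3D
#' rendering), projected on the x-y plane.
#'
#' @param object A `distance_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$distance)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "error (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sensitivity sweep
#'
#' Visible and invisible TRE at best and full coverage against the region
#' threshold.
#'
#' @param sweep A tibble from [sensitivity_sweep()] (possibly with
#'   `viewpoint`/`mode` columns).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("tre_best", "tre_full"),
                              names_to = "coverage", values_to = "tre")
  long$coverage <- sub("^tre_", "", long$coverage)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$tre,
                                          colour = .data$region,
                                          linetype = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "visibility threshold (mm)", y = "TRE (mm)") +
    ggplot2::theme_minimal()
  if ("mode" %in% names(long)) p <- p + ggplot2::facet_wrap(~mode)
  p
}
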