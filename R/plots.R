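#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Compartment densities over time, one line per class, with pulse instants
#' marked. Left/right limit duplicates at pulse nodes are drawn as-is so
#' the vaccination jumps in S and R appear as vertical segments.
#'
#' @param object A `shidr_trajectory`.
#' @param compartments Which columns to draw (default all five classes).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shidr_trajectory
#' @export
autoplot.shidr_trajectory <- function(object,
                                      compartments = c("S", "H", "I", "D", "R"),
                                      ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(
      tibble::as_tibble(object),
      dplyr::all_of(c("t", compartments))
    ),
    cols = -"t", names_to = "compartment", values_to = "density"
  )
  long$compartment <- factor(long$compartment, levels = compartments)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$t, y = .data$density,
    colour = .data$compartment
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot threshold surfaces
#'
#' Heatmaps of the two reproduction numbers over the `(phi, rho)` grid of a
#' [sweep_thresholds()] result, with the unit contour overlaid where it
#' crosses the grid.
#'
#' @param object A `shidr_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object faceted by threshold.
#' @method autoplot shidr_sweep
#' @export
autoplot.shidr_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
    cols = c("R1", "R2"),
    names_to = "threshold", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$phi, y = .data$rho,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~threshold) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "pulse proportion phi", y = "saturation rho") +
    ggplot2::theme_minimal()
}

#' @export
plot.shidr_trajectory <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.shidr_sweep <- function(x, ...) print(autoplot(x, ...))
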