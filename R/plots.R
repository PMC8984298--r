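#' Plot population time series
#'
#' Mean (or single-realization) subpopulation counts against time in days,
#' coloured by compartment, in the style of standard spheroid population
#' panels: living and dead totals, red split into cycling and arrested,
#' yellow and green.
#'
#' @param object a `spheroid_sim` or `spheroid_ensemble`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spheroid_sim <- function(object, ...) {
  plot_population_series(tidy(object))
}

#' @rdname autoplot.spheroid_sim
#' @export
autoplot.spheroid_ensemble <- function(object, ...) {
  series <- tidy(object) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("n_"), mean),
                     .groups = "drop")
  plot_population_series(series)
}

plot_population_series <- function(series) {
  long <- series |>
    tidyr::pivot_longer(dplyr::starts_with("n_"),
                        names_to = "population", values_to = "count") |>
    dplyr::mutate(population = sub("^n_", "", .data$population))
  pal <- c(living = "black", dead = "cyan3", red = "red3",
           cycling_red = "salmon", arrested = "darkred",
           yellow = "gold2", green = "green4")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h / 24, .data$count,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "time (days)", y = "agents", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot periphery-referenced radial profiles
#'
#' @param profiles output of [radial_profiles()].
#' @return A ggplot object faceted by time, profiles coloured by
#'   subpopulation with a +/- 1 sd ribbon where available.
#' @export
plot_radial_profiles <- function(profiles) {
  pal <- c(nutrient = "black", red_cycling = "red3", red_arrested = "darkred",
           yellow = "gold2", green = "green4")
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$p_um, .data$mean,
                               colour = .data$subpopulation,
                               fill = .data$subpopulation)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean - .data$sd, 0),
      ymax = .data$mean + .data$sd), alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ time_h, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "depth from periphery p (um)",
                  y = "relative density / nutrient", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rasterized cross-section
#'
#' Composites the red/yellow/green/dead channels of a
#' [rasterize_cross_section()] image into an RGB raster (dead agents in
#' cyan, matching the usual presentation).
#'
#' @param img a `spheroid_image`.
#' @return A ggplot object.
#' @export
plot_cross_section <- function(img) {
  r <- pmin(img[, , "red"] + img[, , "yellow"], 1)
  g <- pmin(img[, , "green"] + img[, , "yellow"] + img[, , "dead"], 1)
  b <- pmin(img[, , "dead"], 1)
  # transpose so rows become image y
  rgb <- grDevices::rgb(t(r), t(g), t(b))
  dim(rgb) <- rev(dim(r))
  npix <- dim(img)[1]
  half <- (npix - 1) / 2
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rgb[rev(seq_len(nrow(rgb))), ],
                               xmin = -half, xmax = half,
                               ymin = -half, ymax = half) +
    ggplot2::coord_fixed(xlim = c(-half, half), ylim = c(-half, half)) +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
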