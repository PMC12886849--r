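#' Plot a similarity schedule
#'
#' Mean pairwise similarity against lag, with point size showing the number
#' of contributing year pairs.
#'
#' @param object A [mean_similarity_by_lag()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_schedule <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$similarity)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "lag (years)", y = "mean similarity",
                  size = "year pairs") +
    ggplot2::theme_minimal()
}

#' Plot a breakpoint scan
#'
#' Median turnover change per breakpoint year with its exact confidence
#' interval, one panel per stratum. Negative values mean turnover
#' decelerated since the breakyear; intervals excluding zero mark
#' significant change under the two-sided sign test.
#'
#' @param object A [breakpoint_scan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breakpoint_scan <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$median_delta))
  ggplot2::ggplot(dat, ggplot2::aes(.data$breakyear, .data$median_delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0, colour = "grey40"
    ) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "breakpoint year",
                  y = "median turnover change (per year)") +
    ggplot2::theme_minimal()
}

#' Plot a turnover response surface
#'
#' Predicted turnover rate over the (degradation, shift-rate) plane for the
#' selected polynomial order.
#'
#' @param object A [fit_surface()] object.
#' @param order Polynomial order to display (default: selected).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.turnover_surface <- function(object, order = object$order, ...) {
  grid <- predict(object, order = order)
  ggplot2::ggplot(grid, ggplot2::aes(.data$d, .data$v, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "environmental degradation d",
                  y = "environmental rate of change v",
                  fill = "turnover\nrate") +
    ggplot2::theme_minimal()
}

#' @export
plot.breakpoint_scan <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.turnover_surface <- function(x, ...) print(autoplot(x, ...))
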