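#' Plot calibrated stem water content series
#'
#' Time series of temperature-corrected volumetric water content, one colour
#' per tree — the standard first look at a dry-down record.
#'
#' @param calibrated Output of [calibrate_series()] (or the `theta_true`
#'   element of a scenario).
#' @param trees Optional tree metadata to facet by plant type.
#' @return A ggplot object.
#' @export
plot_series <- function(calibrated, trees = NULL) {
  check_columns(calibrated, c("tree_id", "timestamp", "theta"), "calibrated")
  dat <- calibrated
  if (!is.null(trees))
    dat <- dplyr::left_join(dat, dplyr::select(trees, "tree_id", "group"),
                            by = "tree_id")
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$timestamp, .data$theta,
                                         colour = .data$tree_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = NULL,
                  y = expression(theta[T] ~ (m^3 ~ m^-3)),
                  colour = "tree") +
    ggplot2::theme_minimal()
  if (!is.null(trees)) p <- p + ggplot2::facet_wrap(~group, ncol = 1)
  p
}

#' Plot daily discharge capacity against hydration status
#'
#' Scatter of daily relative discharge capacity versus daily-maximum RWC,
#' with the strain bands (severe < 5%, high 5-10%, moderate 10-20%) and the
#' high-hydration exclusion cutoff marked.
#'
#' @param strain_days Output of [capacity_series()].
#' @param rwc_exclude Exclusion cutoff drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_strain <- function(strain_days, rwc_exclude = 0.95) {
  check_columns(strain_days, c("rwc_day_max", "capacity_pct", "tree_id"),
                "strain_days")
  ggplot2::ggplot(strain_days,
                  ggplot2::aes(.data$rwc_day_max, .data$capacity_pct,
                               colour = .data$tree_id)) +
    ggplot2::geom_hline(yintercept = c(5, 10, 20),
                        linetype = c("solid", "solid", "dashed"),
                        colour = c("darkred", "red", "orange")) +
    ggplot2::geom_vline(xintercept = rwc_exclude, linetype = "dashed",
                        colour = "blue") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "daily maximum RWC (-)",
                  y = "discharge capacity (% of maximum)",
                  colour = "tree") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.soil_threshold
#' @method autoplot soil_smooth
#' @export
autoplot.soil_smooth <- function(object, ...) {
  grid <- tidy(object)
  aug <- augment(object)
  ggplot2::ggplot(grid, ggplot2::aes(.data$soil_vwc, .data$fitted)) +
    ggplot2::geom_point(data = aug,
                        ggplot2::aes(.data$soil_vwc, .data$stem_rwc),
                        alpha = 0.2, size = 0.7) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = expression(soil ~ VWC ~ (m^3 ~ m^-3)),
                  y = "stem RWC (-)") +
    ggplot2::theme_minimal()
}

#' Plot the derivative grid and detected soil-moisture threshold
#'
#' For a `soil_smooth`, draws the fitted response with its confidence
#' ribbon over the data; for a `soil_threshold`, draws the first-derivative
#' grid with its simulation CI, shades the qualifying run, and marks the
#' detected threshold.
#'
#' @param object A `soil_smooth` or `soil_threshold`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot soil_threshold
#' @export
autoplot.soil_threshold <- function(object, ...) {
  g <- tidy(object)
  p <- ggplot2::ggplot(g, ggplot2::aes(.data$soil_vwc, .data$derivative)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.25, fill = "firebrick") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = expression(soil ~ VWC ~ (m^3 ~ m^-3)),
                  y = "d(stem RWC) / d(soil VWC)") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold_vwc))
    p <- p + ggplot2::geom_vline(xintercept = object$threshold_vwc,
                                 linetype = "dashed", colour = "red")
  p
}
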