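#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a soil-to-stem smooth fit
#'
#' One row per fitted-grid point: the predicted stem RWC with pointwise 95%
#' confidence limits over the observed soil VWC range.
#'
#' @param x A `soil_smooth` from [fit_smooth()].
#' @param n_grid Number of grid points (default 200).
#' @param ... Unused.
#' @return A tibble `soil_vwc`, `fitted`, `ci_lower`, `ci_upper`.
#' @method tidy soil_smooth
#' @export
tidy.soil_smooth <- function(x, n_grid = 200, ...) {
  grid <- seq(x$x_range[1], x$x_range[2], length.out = n_grid)
  p <- stats::predict(x$gam, data.frame(x = grid), se.fit = TRUE)
  z <- stats::qnorm(0.975)
  tibble::tibble(soil_vwc = grid, fitted = as.numeric(p$fit),
                 ci_lower = as.numeric(p$fit - z * p$se.fit),
                 ci_upper = as.numeric(p$fit + z * p$se.fit))
}

#' Glance at a soil-to-stem smooth fit
#'
#' @param x A `soil_smooth`.
#' @param ... Unused.
#' @return A one-row tibble: `group`, `n`, `k`, `edf`, `r_squared`,
#'   `smoothing_parameter`, `method`.
#' @method glance soil_smooth
#' @export
glance.soil_smooth <- function(x, ...) {
  s <- summary(x$gam)
  tibble::tibble(group = x$group, n = x$n, k = x$k,
                 edf = sum(x$gam$edf),
                 r_squared = s$r.sq,
                 smoothing_parameter = unname(x$gam$sp[1]),
                 method = as.character(x$gam$method))
}

#' Augment the training pairs with fitted values and residuals
#'
#' @param x A `soil_smooth`.
#' @param ... Unused.
#' @return A tibble `soil_vwc`, `stem_rwc`, `.fitted`, `.resid`.
#' @method augment soil_smooth
#' @export
augment.soil_smooth <- function(x, ...) {
  tibble::tibble(soil_vwc = x$gam$model$x, stem_rwc = x$gam$model$y,
                 .fitted = stats::fitted(x$gam),
                 .resid = stats::residuals(x$gam))
}

#' Tidy a detected soil-moisture threshold
#'
#' Returns the per-grid-point criteria trace in wet-to-dry scan order.
#'
#' @param x A `soil_threshold` from [detect_threshold()].
#' @param ... Unused.
#' @return A tibble with `soil_vwc`, `derivative`, `ci_lower`, `ci_upper`,
#'   `significant`, `strong_quartile`, `qualifying`, `in_run`.
#' @method tidy soil_threshold
#' @export
tidy.soil_threshold <- function(x, ...) {
  tibble::as_tibble(x$criteria)
}

#' Glance at a detected soil-moisture threshold
#'
#' @param x A `soil_threshold`.
#' @param ... Unused.
#' @return A one-row tibble: `threshold_vwc`, `detected`, `run_length`,
#'   `quartile_cutoff`, `min_run`.
#' @method glance soil_threshold
#' @export
glance.soil_threshold <- function(x, ...) {
  tibble::tibble(
    threshold_vwc = x$threshold_vwc,
    detected = !is.na(x$threshold_vwc),
    run_length = if (is.null(x$qualifying_run)) 0L
      else x$qualifying_run[2] - x$qualifying_run[1] + 1L,
    quartile_cutoff = x$quartile_cutoff,
    min_run = x$min_run)
}
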