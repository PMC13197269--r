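#' Calibration model for FDR stem water content sensors
#'
#' Bundles the coefficients that convert dielectric permittivity measured in
#' woody tissue into volumetric water content, together with the empirical
#' temperature correction. The defaults are a published general calibration
#' for FDR sensors in both dicot sapwood and palm stem tissue:
#' \deqn{\theta_{stem} = 0.2227\sqrt{\varepsilon_{stem}} - 0.396}
#' with a linear temperature correction
#' \deqn{\theta_T = \theta_{stem} + (T_{stem} - T_{ref})\,\beta,\qquad
#'       \beta = -0.000974\ \mathrm{m^3\,m^{-3}\,{}^{\circ}C^{-1}}.}
#' All coefficients are overridable so users can supply a sensor- or
#' species-specific re-fit.
#'
#' @param slope Slope of volumetric water content on \eqn{\sqrt{\varepsilon}}
#'   (m\eqn{^3} m\eqn{^{-3}} per unit \eqn{\sqrt{\varepsilon}}). Must be > 0.
#' @param intercept Intercept of the calibration line (m\eqn{^3} m\eqn{^{-3}}).
#' @param beta Temperature-effect slope (m\eqn{^3} m\eqn{^{-3}} per degree C).
#' @param t_ref Reference temperature of the laboratory calibration (degrees C).
#'
#' @return An object of class `fdr_calibration` (a named list of the four
#'   coefficients).
#' @examples
#' m <- calibration_model()
#' calibrate_theta(4, m)
#' @export
calibration_model <- function(slope = 0.2227, intercept = -0.396,
                              beta = -0.000974, t_ref = 25) {
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope) || slope <= 0)
    stop("`slope` must be a single positive number", call. = FALSE)
  for (nm in c("intercept", "beta", "t_ref")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, beta = beta,
                 t_ref = t_ref),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat("<fdr_calibration>\n")
  cat(sprintf("  theta_stem = %.4g * sqrt(epsilon) %+.4g\n", x$slope, x$intercept))
  cat(sprintf("  theta_T    = theta_stem + (T_stem - %.4g) * %.4g\n",
              x$t_ref, x$beta))
  invisible(x)
}

#' Convert dielectric permittivity to volumetric water content
#'
#' Applies the square-root calibration line \eqn{\theta = a\sqrt{\varepsilon} + b}.
#' The result is the uncorrected water content at the calibration reference
#' temperature; apply [temperature_correct()] for field conditions.
#'
#' @param epsilon Dielectric permittivity (dimensionless, > 0). Vectorised;
#'   `NA` propagates.
#' @param model A [calibration_model()].
#' @return Volumetric water content, m\eqn{^3} m\eqn{^{-3}}.
#' @examples
#' calibrate_theta(4) # 0.0494
#' @export
calibrate_theta <- function(epsilon, model = calibration_model()) {
  stopifnot(inherits(model, "fdr_calibration"))
  if (any(epsilon <= 0, na.rm = TRUE))
    stop("permittivity must be > 0", call. = FALSE)
  model$slope * sqrt(epsilon) + model$intercept
}

#' Temperature-correct volumetric water content
#'
#' The dielectric constant of wet tissue decreases with temperature, so raw
#' calibrated readings drift with stem temperature. The correction is affine:
#' \eqn{\theta_T = \theta_{stem} + (T_{stem} - T_{ref})\beta}.
#'
#' @param theta_stem Uncorrected volumetric water content, m\eqn{^3} m\eqn{^{-3}}.
#' @param t_stem Stem temperature, degrees C. Vectorised with `theta_stem`.
#' @inheritParams calibrate_theta
#' @return Temperature-corrected water content, m\eqn{^3} m\eqn{^{-3}}.
#' @examples
#' temperature_correct(0.5, 30) # 0.49513
#' @export
temperature_correct <- function(theta_stem, t_stem, model = calibration_model()) {
  stopifnot(inherits(model, "fdr_calibration"))
  theta_stem + (t_stem - model$t_ref) * model$beta
}

#' Invert the calibration chain
#'
#' Recovers the dielectric permittivity that would produce a given
#' temperature-corrected water content at a given stem temperature. Exact
#' inverse of [calibrate_theta()] followed by [temperature_correct()]; used by
#' the scenario generator to synthesise raw sensor readings from a known
#' water-content series.
#'
#' @param theta_t_corrected Temperature-corrected water content,
#'   m\eqn{^3} m\eqn{^{-3}}.
#' @param t_stem Stem temperature, degrees C.
#' @inheritParams calibrate_theta
#' @return Dielectric permittivity (dimensionless).
#' @examples
#' invert_calibration(0.0494, 25) # 4
#' @export
invert_calibration <- function(theta_t_corrected, t_stem,
                               model = calibration_model()) {
  stopifnot(inherits(model, "fdr_calibration"))
  theta_stem <- theta_t_corrected - (t_stem - model$t_ref) * model$beta
  root <- (theta_stem - model$intercept) / model$slope
  if (any(root <= 0, na.rm = TRUE))
    stop("water content at or below the calibration intercept; ",
         "permittivity is undefined", call. = FALSE)
  root^2
}

#' Calibrate a raw sensor data frame
#'
#' Applies [calibrate_theta()] and [temperature_correct()] pointwise to a
#' tidy table of raw FDR readings. Missing raw values stay missing; no
#' interpolation happens at this stage (daily aggregation owns the gap
#' policy). Calibrated values outside \eqn{[0, 1]} are flagged in
#' `out_of_range` rather than silently clipped, unless `clip = TRUE`.
#'
#' @param sensor A data frame with columns `tree_id`, `timestamp` (POSIXct),
#'   `epsilon`, `t_stem`.
#' @param model A [calibration_model()].
#' @param clip If `TRUE`, clip calibrated values into \eqn{[0, 1]}; default
#'   keeps them as-is and flags them.
#' @return A tibble `tree_id`, `timestamp`, `theta`, `out_of_range`.
#' @export
calibrate_series <- function(sensor, model = calibration_model(),
                             clip = FALSE) {
  check_columns(sensor, c("tree_id", "timestamp", "epsilon", "t_stem"),
                "sensor")
  if (all(is.na(sensor$epsilon)))
    stop("all permittivity values are missing", call. = FALSE)
  out <- sensor |>
    dplyr::mutate(
      theta = temperature_correct(
        calibrate_theta(.data$epsilon, model), .data$t_stem, model),
      out_of_range = !is.na(.data$theta) & (.data$theta < 0 | .data$theta > 1)
    ) |>
    dplyr::select("tree_id", "timestamp", "theta", "out_of_range")
  if (clip) out$theta <- pmin(pmax(out$theta, 0), 1)
  tibble::as_tibble(out)
}

# shared column check with a readable error
check_columns <- function(df, cols, what) {
  if (!is.data.frame(df))
    stop(sprintf("`%s` must be a data frame", what), call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("`%s` is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
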