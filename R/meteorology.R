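#' Saturation vapour pressure (Tetens)
#'
#' Tetens approximation over liquid water,
#' \eqn{e_{sat}(t) = 0.6108\,\exp(17.27\,t/(t + 237.3))} kPa.
#'
#' @param t_air Air temperature, degrees C.
#' @return Saturation vapour pressure, kPa.
#' @export
esat_tetens <- function(t_air) {
  0.6108 * exp(17.27 * t_air / (t_air + 237.3))
}

#' Vapour pressure deficit
#'
#' The drying power of air: \eqn{VPD = e_{sat}(t)\,(1 - RH/100)} with the
#' Tetens saturation curve. Non-negative by construction, zero at saturation.
#'
#' @param t_air Air temperature, degrees C. Vectorised.
#' @param rh Relative humidity, percent in \eqn{[0, 100]}.
#' @return VPD in kPa.
#' @examples
#' vpd(25, 50) # about 1.584
#' @export
vpd <- function(t_air, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE))
    stop("relative humidity must be within [0, 100]", call. = FALSE)
  esat_tetens(t_air) * (1 - rh / 100)
}

#' Daily maximum vapour pressure deficit
#'
#' Summarises a sub-daily meteorological series to one value per calendar
#' day: the within-day 99th percentile of VPD, a trimmed daily maximum robust
#' to single-sample spikes. Days with fewer than `completeness` of the
#' expected samples are dropped with a warning, mirroring the day-retention
#' rule used for the stem series.
#'
#' @param meteo Data frame with columns `timestamp`, `t_air`, `rh`.
#' @param completeness Minimum fraction of expected samples for a day to be
#'   retained (default 0.8).
#' @param cadence_minutes Sampling interval in minutes; inferred from the
#'   timestamps when `NULL`.
#' @return A tibble `date`, `vpd_max` (kPa), `n_samples`.
#' @export
daily_max_vpd <- function(meteo, completeness = 0.8, cadence_minutes = NULL) {
  check_columns(meteo, c("timestamp", "t_air", "rh"), "meteo")
  if (is.null(cadence_minutes)) cadence_minutes <- infer_cadence(meteo$timestamp)
  expected <- 1440 / cadence_minutes
  out <- meteo |>
    dplyr::mutate(vpd = vpd(.data$t_air, .data$rh),
                  date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::filter(!is.na(.data$vpd)) |>
    dplyr::summarise(vpd_max = percentile(.data$vpd, 99),
                     n_samples = dplyr::n(), .by = "date")
  dropped <- out$n_samples < completeness * expected
  if (any(dropped))
    warning(sprintf("dropping %d day(s) below the %g%% completeness floor",
                    sum(dropped), 100 * completeness), call. = FALSE)
  tibble::as_tibble(out[!dropped, ])
}

# constant cadence in minutes from a timestamp vector
infer_cadence <- function(ts) {
  d <- diff(sort(unique(as.numeric(ts)))) / 60
  if (!length(d)) stop("cannot infer cadence from a single timestamp",
                       call. = FALSE)
  cad <- min(d)
  if (any(abs(d %% cad) > 1e-6 & abs(d %% cad - cad) > 1e-6))
    stop("timestamps are not on a constant cadence", call. = FALSE)
  cad
}
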