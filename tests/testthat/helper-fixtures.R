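# Shared fixtures, all built in code.

# short scenario: season scaled to the reduced length so the dry-down still
# crosses the refill cutoff when decay is raised
short_config <- function(n_days = 30, seed = 1L, ...) {
  wet_end <- max(1, round(n_days * 0.2))
  scenario_config(
    n_days = n_days,
    season = list(wet_end = wet_end,
                  rewet_start = max(wet_end, n_days - 2)),
    seed = seed, ...)
}

# a regular 15-min timestamp axis over n days
stamp_axis <- function(n_days, cadence = 15, start = "2023-07-01") {
  origin <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  origin + 60 * cadence * (seq_len(n_days * (1440 / cadence)) - 1)
}

# calibrated series from a theta function of fractional hour-of-day and day
make_calibrated <- function(n_days, theta_fun, tree_id = "t1",
                            cadence = 15) {
  ts <- stamp_axis(n_days, cadence)
  h <- (as.numeric(ts - ts[1]) / 3600) %% 24
  d <- floor(as.numeric(ts - ts[1]) / 86400) + 1
  tibble::tibble(tree_id = tree_id, timestamp = ts,
                 theta = theta_fun(h, d))
}

# strain-day table straight from capacities and daily-max RWC
make_strain_days <- function(capacity_pct, rwc, tree_id = "t1",
                             rwc_exclude = 0.95) {
  n <- length(capacity_pct)
  days <- tibble::tibble(
    tree_id = tree_id,
    date = as.Date("2023-07-01") + seq_len(n) - 1,
    daily_range = capacity_pct / 100,
    rwc_day_max = rwc)
  capacity_series(days,
                  diurnal_delta_max = tibble::tibble(tree_id = tree_id,
                                                     diurnal_delta = 1),
                  rwc_exclude = rwc_exclude)
}

# hand-built derivative grid in the VWC direction; `drying` gives the
# drying-direction derivative the detection rule reasons about
make_deriv_grid <- function(soil_vwc, drying, half_width = 0.1) {
  tibble::tibble(
    soil_vwc = soil_vwc,
    derivative = -drying,
    ci_lower = -drying - half_width,
    ci_upper = -drying + half_width,
    fitted = NA_real_)
}
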