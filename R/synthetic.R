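#' Default tree set for synthetic scenarios
#'
#' Seven trees — two palms and five dicots — whose geometry, wood density and
#' embedded hydraulic ground truth emulate a seasonal dry-down field study of
#' subcanopy trees in eastern Amazonia: palms with high turgid water content
#' (about 0.67-0.73 m\eqn{^3} m\eqn{^{-3}}) and large diurnal discharge, and
#' dicots spanning a wood-density gradient with much smaller storage. The
#' truth columns (`theta_turgid_true`, `theta_dry_true`, `diurnal_amp_true`,
#' `rwc_crit_true`) are what parameter-recovery tests compare pipeline
#' estimates against. Trees whose `rwc_crit_true` lies below the reachable
#' minimum RWC never cross the critical threshold; the pipeline should report
#' a censored bound for them.
#'
#' @return A tibble, one row per tree, with columns `tree_id`, `group`,
#'   `height` (m), `dbh` (m), `wood_density` (g cm\eqn{^{-3}}),
#'   `sapwood_depth` (m, `NA` for palms), and the four truth columns.
#' @export
scenario_trees <- function() {
  tibble::tibble(
    tree_id = c("palm_a", "palm_b", "dicot_a", "dicot_b", "dicot_c",
                "dicot_d", "dicot_e"),
    group = c("palm", "palm", rep("dicot", 5)),
    height = c(20, 13, 18, 22, 17, 15, 14),
    dbh = c(0.22, 0.22, 0.18, 0.25, 0.20, 0.17, 0.16),
    wood_density = c(0.63, 0.29, 0.54, 0.82, 0.69, 0.75, 0.75),
    sapwood_depth = c(NA, NA, 0.029, 0.040, 0.032, 0.027, 0.025),
    theta_turgid_true = c(0.673, 0.728, 0.459, 0.391, 0.485, 0.366, 0.352),
    theta_dry_true = c(0.436, 0.521, 0.358, 0.293, 0.400, 0.306, 0.292),
    diurnal_amp_true = c(0.058, 0.038, 0.028, 0.025, 0.012, 0.016, 0.013),
    rwc_crit_true = c(0.68, 0.60, 0.81, 0.78, 0.72, 0.72, 0.72))
}

#' Scenario configuration for the synthetic-data generator
#'
#' Collects every knob of the generator with defaults emulating the study
#' conditions of a 163-day El Nino dry-down at 15-min sensor resolution: a
#' wet phase, a long rainless dry-down during which soil moisture decays
#' exponentially past the stem refill cutoff, and a rewetting phase in which
#' rain recharges the soil and stems rehydrate.
#'
#' @param n_days Length of the scenario in days (>= 2; default 163).
#' @param cadence_minutes Sensor cadence; must divide 1440 (default 15).
#' @param trees Tree table as from [scenario_trees()].
#' @param season List: `wet_end` (last all-wet day) and `rewet_start` (first
#'   day of the rewetting phase).
#' @param soil List: `vwc_initial`, `vwc_max`, `vwc_floor`
#'   (m\eqn{^3} m\eqn{^{-3}}), `decay_rate` (day\eqn{^{-1}}),
#'   `recharge_per_mm` (m\eqn{^3} m\eqn{^{-3}} per mm rain), `depths_cm`.
#' @param climate List: stem and air temperature sinusoid mean/amplitude
#'   (degrees C), `rh_max`/`rh_min` (%), `rain_rate` (events day\eqn{^{-1}}
#'   in wet phases), `rain_depth_mm` (mean event depth).
#' @param noise List: `epsilon_sd` (permittivity noise SD), `soil_sd`
#'   (soil VWC noise SD).
#' @param refill_cutoff Soil VWC below which stems can no longer refill
#'   overnight (m\eqn{^3} m\eqn{^{-3}}; default 0.19).
#' @param decline List shaping the post-cutoff decline of nightly-maximum
#'   water content: `onset` and `width` (severity-days) of the logistic
#'   decline, `severity_width` (m\eqn{^3} m\eqn{^{-3}}) of the soil-severity
#'   ramp, `recovery_rate` (day\eqn{^{-1}}) of rehydration above the cutoff.
#' @param amplitude List shaping diurnal discharge: `floor` (residual
#'   fraction of amplitude below the critical RWC), `width` (RWC units of
#'   the logistic shut-down), `day_var` (day-to-day amplitude variability
#'   fraction).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_days = 163, cadence_minutes = 15,
                            trees = scenario_trees(),
                            season = list(wet_end = 30, rewet_start = 140),
                            soil = list(vwc_initial = 0.30, vwc_max = 0.32,
                                        vwc_floor = 0.12, decay_rate = 0.014,
                                        recharge_per_mm = 0.0015,
                                        depths_cm = c(100, 250, 400)),
                            climate = list(t_stem_mean = 28, t_stem_amp = 4,
                                           t_air_mean = 26, t_air_amp = 4,
                                           rh_max = 98, rh_min = 65,
                                           rain_rate = 0.7,
                                           rain_depth_mm = 10),
                            noise = list(epsilon_sd = 0.005, soil_sd = 0.002),
                            refill_cutoff = 0.19,
                            decline = list(onset = 5, width = 2.5,
                                           severity_width = 0.005,
                                           recovery_rate = 0.25),
                            amplitude = list(floor = 0.03, width = 0.004,
                                             day_var = 0.2),
                            seed = 1L) {
  cfg <- list(n_days = n_days, cadence_minutes = cadence_minutes,
              trees = trees, season = season, soil = soil, climate = climate,
              noise = noise, refill_cutoff = refill_cutoff,
              decline = decline, amplitude = amplitude,
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid scenario config: `%s` %s", field, msg),
         call. = FALSE)
  if (!is.numeric(cfg$n_days) || cfg$n_days < 2)
    fail("n_days", "must be at least 2")
  if (1440 %% cfg$cadence_minutes != 0)
    fail("cadence_minutes", "must divide 1440")
  tr <- cfg$trees
  check_columns(tr, c("tree_id", "group", "height", "dbh",
                      "theta_turgid_true", "theta_dry_true",
                      "diurnal_amp_true", "rwc_crit_true"), "trees")
  if (anyDuplicated(tr$tree_id)) fail("trees$tree_id", "must be unique")
  with(tr, {
    if (any(!(theta_dry_true > 0 & theta_dry_true < theta_turgid_true &
              theta_turgid_true < 1)))
      fail("trees", "needs 0 < theta_dry_true < theta_turgid_true < 1")
    if (any(rwc_crit_true >= 1)) fail("trees$rwc_crit_true", "must be < 1")
    if (any(diurnal_amp_true < 0))
      fail("trees$diurnal_amp_true", "must be >= 0")
  })
  if (cfg$season$wet_end < 0 || cfg$season$rewet_start > cfg$n_days + 1 ||
      cfg$season$wet_end > cfg$season$rewet_start)
    fail("season", "needs 0 <= wet_end <= rewet_start <= n_days + 1")
  s <- cfg$soil
  if (!(s$vwc_floor > 0 && s$vwc_floor <= s$vwc_initial &&
        s$vwc_initial <= s$vwc_max && s$vwc_max < 1))
    fail("soil", "needs 0 < vwc_floor <= vwc_initial <= vwc_max < 1")
  if (s$decay_rate < 0) fail("soil$decay_rate", "must be >= 0")
  if (s$recharge_per_mm < 0) fail("soil$recharge_per_mm", "must be >= 0")
  if (cfg$noise$epsilon_sd < 0 || cfg$noise$soil_sd < 0)
    fail("noise", "standard deviations must be >= 0")
  if (cfg$climate$rain_rate < 0) fail("climate$rain_rate", "must be >= 0")
  if (cfg$refill_cutoff <= 0 || cfg$refill_cutoff >= 1)
    fail("refill_cutoff", "must lie in (0, 1)")
  invisible(cfg)
}

#' Generate a synthetic scenario with known ground truth
#'
#' Builds raw sensor, soil and meteorological series whose statistical
#' structure mirrors a seasonal dry-down with diurnal discharge/refill
#' cycles. Per tree, temperature-corrected water content is a seasonal
#' nightly-maximum baseline — equal to the turgid value while the soil can
#' supply overnight refill, declining logistically (in accumulated
#' severity-days) toward the dry value once soil VWC falls below the refill
#' cutoff, and relaxing back up after rain recharges the soil — minus a
#' midday discharge dip whose amplitude shuts down smoothly to a few percent
#' of maximum when nightly-maximum RWC falls below the tree's critical RWC.
#' The water-content series is pushed through the exact inverse of the
#' calibration chain at the simulated stem temperature, and Gaussian
#' permittivity noise is added. Deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @param start_date First day of the scenario (default `"2023-07-01"`).
#' @return A list of class `stem_scenario` with elements `sensor`
#'   (`tree_id`, `timestamp`, `epsilon`, `t_stem`), `soil` (`timestamp`,
#'   `depth_cm`, `vwc`), `meteo` (`timestamp`, `t_air`, `rh`,
#'   `precipitation`), `trees` (metadata), `truth` (per-tree ground truth),
#'   `theta_true` (noise-free calibrated water content), and `config`.
#' @examples
#' sc <- generate_scenario(scenario_config(n_days = 5))
#' head(sc$sensor)
#' @export
generate_scenario <- function(config = scenario_config(),
                              start_date = "2023-07-01") {
  validate_scenario_config(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(config$seed)

  n_days <- config$n_days
  spd <- 1440 %/% config$cadence_minutes            # samples per day
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  ts <- origin + 60 * config$cadence_minutes * seq_len(n_days * spd) -
    60 * config$cadence_minutes
  hour <- (as.numeric(ts - origin) / 3600) %% 24
  day_of <- rep(seq_len(n_days), each = spd)

  # --- rain: Poisson events in the wet phases only -------------------------
  cl <- config$climate
  phase_wet <- seq_len(n_days) <= config$season$wet_end |
    seq_len(n_days) >= config$season$rewet_start
  n_events <- stats::rpois(n_days, ifelse(phase_wet, cl$rain_rate, 0))
  precip <- numeric(n_days * spd)
  for (d in which(n_events > 0)) {
    at <- (d - 1) * spd + sample.int(spd, n_events[d], replace = TRUE)
    precip[at] <- precip[at] + stats::rexp(n_events[d], 1 / cl$rain_depth_mm)
  }
  rain_daily <- vapply(split(precip, day_of), sum, numeric(1))

  # --- soil: exponential decay between events, pulse recharge --------------
  so <- config$soil
  hourly_per_step <- config$cadence_minutes / 60
  # deeper horizons dry (and recharge) progressively more slowly
  scale_by_depth <- stats::setNames(
    0.5^(seq_along(so$depths_cm) - 1), so$depths_cm)
  soil_clean <- lapply(so$depths_cm, function(dep) {
    k <- so$decay_rate * scale_by_depth[[as.character(dep)]]
    rch <- so$recharge_per_mm * scale_by_depth[[as.character(dep)]]
    v <- numeric(n_days * spd)
    s <- so$vwc_initial
    for (i in seq_along(v)) {
      s <- so$vwc_floor + (s - so$vwc_floor) * exp(-k * hourly_per_step / 24)
      s <- min(s + rch * precip[i], so$vwc_max)
      v[i] <- s
    }
    v
  })
  names(soil_clean) <- as.character(so$depths_cm)
  soil_daily_mean <- vapply(split(soil_clean[[1]], day_of), mean, numeric(1))

  # --- per-tree stem water content -----------------------------------------
  dc <- config$decline
  am <- config$amplitude
  sev <- stats::plogis((config$refill_cutoff - soil_daily_mean) /
                         dc$severity_width)
  below <- soil_daily_mean < config$refill_cutoff
  L0 <- stats::plogis(dc$onset / dc$width)
  t_stem <- cl$t_stem_mean + cl$t_stem_amp * cos(2 * pi * (hour - 15) / 24)
  dip <- exp(-((hour - 13.5) / 3)^2)
  model <- calibration_model()

  tree_seeds <- sample.int(.Machine$integer.max - 1L, nrow(config$trees))
  sensor <- vector("list", nrow(config$trees))
  theta_true <- vector("list", nrow(config$trees))
  for (j in seq_len(nrow(config$trees))) {
    tr <- config$trees[j, ]
    set.seed(tree_seeds[j])
    delta <- tr$theta_turgid_true - tr$theta_dry_true
    b <- numeric(n_days)
    s_cum <- 0
    b_prev <- tr$theta_turgid_true
    for (d in seq_len(n_days)) {
      if (below[d]) {
        s_cum <- s_cum + sev[d]
        b[d] <- tr$theta_dry_true + delta *
          stats::plogis((dc$onset - s_cum) / dc$width) / L0
        b[d] <- min(b[d], b_prev)      # drydown never rehydrates the stem
      } else {
        b[d] <- b_prev + dc$recovery_rate * (tr$theta_turgid_true - b_prev)
      }
      b_prev <- b[d]
    }
    rwc_night <- b / tr$theta_turgid_true
    gate <- am$floor + (1 - am$floor) *
      stats::plogis((rwc_night - tr$rwc_crit_true) / am$width)
    amp_day <- tr$diurnal_amp_true *
      (1 - am$day_var * stats::runif(n_days)) * gate
    theta <- b[day_of] - amp_day[day_of] * dip
    eps <- invert_calibration(theta, t_stem, model) +
      stats::rnorm(length(theta), sd = config$noise$epsilon_sd)
    eps_min <- (model$intercept / model$slope)^2
    eps <- pmax(eps, eps_min + 1e-6)
    sensor[[j]] <- tibble::tibble(tree_id = tr$tree_id, timestamp = ts,
                                  epsilon = eps, t_stem = t_stem)
    theta_true[[j]] <- tibble::tibble(tree_id = tr$tree_id, timestamp = ts,
                                      theta = theta)
  }

  # soil is logged hourly (TDR pit cadence), coarser than the stem sensors
  hr_idx <- if (config$cadence_minutes <= 60)
    seq(1, length(ts), by = 60 %/% config$cadence_minutes)
  else seq_along(ts)
  soil_noisy <- purrr::imap(soil_clean, function(v, dep) {
    v <- v[hr_idx]
    tibble::tibble(
      timestamp = ts[hr_idx], depth_cm = as.numeric(dep),
      vwc = pmin(pmax(v + stats::rnorm(length(v), sd = config$noise$soil_sd),
                      0.01), 0.99))
  })

  t_air <- cl$t_air_mean + cl$t_air_amp * cos(2 * pi * (hour - 15) / 24)
  rh <- pmin(pmax(
    cl$rh_max - (cl$rh_max - cl$rh_min) * dip +
      stats::rnorm(length(ts), sd = 1), 5), 100)

  truth <- config$trees |>
    dplyr::select("tree_id", "theta_turgid_true", "theta_dry_true",
                  "diurnal_amp_true", "rwc_crit_true") |>
    dplyr::mutate(refill_cutoff_soil_vwc_true = config$refill_cutoff)
  trees_meta <- config$trees |>
    dplyr::select(dplyr::any_of(c("tree_id", "group", "height", "dbh",
                                  "wood_density", "sapwood_depth")))

  structure(list(
    sensor = dplyr::bind_rows(sensor),
    soil = dplyr::bind_rows(soil_noisy),
    meteo = tibble::tibble(timestamp = ts, t_air = t_air, rh = rh,
                           precipitation = precip),
    trees = trees_meta,
    truth = truth,
    theta_true = dplyr::bind_rows(theta_true),
    config = config), class = "stem_scenario")
}

#' @export
print.stem_scenario <- function(x, ...) {
  cat("<stem_scenario>\n")
  cat(sprintf("  %d trees x %d days at %d-min cadence (%d sensor rows)\n",
              nrow(x$trees), x$config$n_days, x$config$cadence_minutes,
              nrow(x$sensor)))
  cat(sprintf("  soil depths: %s cm; seed %d\n",
              paste(x$config$soil$depths_cm, collapse = ", "),
              x$config$seed))
  invisible(x)
}

#' Write a scenario to CSV files
#'
#' Writes the sensor, soil, meteorological, tree-metadata and ground-truth
#' tables in the package's CSV dialects so they round-trip losslessly
#' through [read_sensor_csv()] and friends.
#'
#' @param scenario A `stem_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "stem_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(sensor = file.path(dir, "sensor.csv"),
             soil = file.path(dir, "soil.csv"),
             meteo = file.path(dir, "meteo.csv"),
             trees = file.path(dir, "trees.csv"),
             truth = file.path(dir, "truth.csv"))
  write_csv_iso(scenario$sensor, paths[["sensor"]])
  write_csv_iso(scenario$soil, paths[["soil"]])
  write_csv_iso(scenario$meteo, paths[["meteo"]])
  write_csv_iso(scenario$trees, paths[["trees"]])
  write_csv_iso(scenario$truth, paths[["truth"]])
  invisible(paths)
}
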