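# CSV dialect shared by all readers/writers: comma-separated, UTF-8, "."
# decimal, mandatory header, empty fields for missing values, ISO 8601
# timestamps in UTC.

write_csv_iso <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(~ inherits(.x, "POSIXct")),
    ~ format(.x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  readr::write_csv(df, path, na = "")
  invisible(path)
}

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = col_types, na = c("", "NA"),
                  progress = FALSE)
}

parse_iso_stamp <- function(x, path) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                   "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x))
    stop("unparseable timestamps in ", path, call. = FALSE)
  out
}

#' Read a raw sensor CSV
#'
#' Expects columns `timestamp` (ISO 8601), `tree_id`, `epsilon`, `t_stem`.
#' Validates that every tree's timestamps are strictly increasing on a
#' constant cadence (gaps as missing values are fine; irregular steps are
#' not) and that present permittivities are positive.
#'
#' @param path Path to the CSV file.
#' @return A tibble `tree_id`, `timestamp`, `epsilon`, `t_stem`.
#' @export
read_sensor_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    timestamp = readr::col_character(), tree_id = readr::col_character(),
    epsilon = readr::col_double(), t_stem = readr::col_double()))
  check_columns(df, c("timestamp", "tree_id", "epsilon", "t_stem"),
                basename(path))
  df$timestamp <- parse_iso_stamp(df$timestamp, path)
  if (nrow(df)) validate_cadence(df, path)
  if (any(df$epsilon <= 0, na.rm = TRUE))
    stop("non-positive permittivity values in ", path, call. = FALSE)
  dplyr::select(df, "tree_id", "timestamp", "epsilon", "t_stem")
}

validate_cadence <- function(df, path) {
  bad <- df |>
    dplyr::summarise(ok = {
      d <- diff(as.numeric(.data$timestamp))
      length(d) == 0 || (all(d > 0) && all(abs(d %% min(d)) < 1e-6 |
                                             abs(d %% min(d) - min(d)) < 1e-6))
    }, .by = "tree_id") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad))
    stop("irregular or non-increasing timestamps in ", path, " for tree(s): ",
         paste(bad$tree_id, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a soil-moisture CSV
#'
#' Long format: `timestamp`, `depth_cm`, `vwc` (m\eqn{^3} m\eqn{^{-3}}).
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_soil_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    timestamp = readr::col_character(), depth_cm = readr::col_double(),
    vwc = readr::col_double()))
  check_columns(df, c("timestamp", "depth_cm", "vwc"), basename(path))
  df$timestamp <- parse_iso_stamp(df$timestamp, path)
  if (any(df$vwc <= 0 | df$vwc >= 1, na.rm = TRUE))
    stop("soil VWC must lie in (0, 1) in ", path, call. = FALSE)
  df
}

#' Read a meteorological CSV
#'
#' Columns `timestamp`, `t_air` (degrees C), `rh` (%), `precipitation`
#' (mm per interval).
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_meteo_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    timestamp = readr::col_character(), t_air = readr::col_double(),
    rh = readr::col_double(), precipitation = readr::col_double()))
  check_columns(df, c("timestamp", "t_air", "rh", "precipitation"),
                basename(path))
  df$timestamp <- parse_iso_stamp(df$timestamp, path)
  if (any(df$rh < 0 | df$rh > 100, na.rm = TRUE))
    stop("relative humidity outside [0, 100] in ", path, call. = FALSE)
  if (any(df$precipitation < 0, na.rm = TRUE))
    stop("negative precipitation in ", path, call. = FALSE)
  df
}

#' Read a tree-metadata CSV
#'
#' Columns `tree_id`, `group` (palm/dicot), `height` (m), `dbh` (m), and
#' optionally `wood_density` (g cm\eqn{^{-3}}) and `sapwood_depth` (m).
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_trees_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    tree_id = readr::col_character(), group = readr::col_character(),
    .default = readr::col_double()))
  check_columns(df, c("tree_id", "group", "height", "dbh"), basename(path))
  df$group <- match_group(df$group)
  df
}

#' Run the full analysis pipeline
#'
#' Executes calibration, daily summarising, storage metrics, strain
#' classification and thresholds, soil-moisture breakpoint detection, and
#' palm-vs-dicot contrasts in one call, optionally writing every result
#' table plus a reproducibility log to `out_dir`.
#'
#' @param sensor,soil,meteo,trees Input tables (see the `read_*_csv()`
#'   readers), or a `stem_scenario` passed as `sensor` with the rest `NULL`.
#' @param out_dir Optional output directory; when given, writes
#'   `storage_metrics.csv`, `strain_days.csv`, `strain_thresholds.csv`,
#'   `daily_summaries.csv`, `threshold.json`, `contrasts.csv` and `run_log.json`.
#' @param model [calibration_model()] to apply.
#' @param depth_cm Soil depth for the breakpoint analysis (default 100).
#' @param k Spline basis dimension (default 6).
#' @param n_grid,n_draws Derivative grid size and posterior draws.
#' @param rwc_exclude High-hydration exclusion cutoff (default 0.95).
#' @param completeness Day-retention floor (default 0.8).
#' @param n_perm Permutation iterations (default 5000).
#' @param seed Seed driving the derivative CIs and permutation tests.
#' @param contrast_metrics Per-tree metric columns to contrast between
#'   groups.
#' @return A list of class `stem_pipeline` with elements `calibrated`,
#'   `days`, `metrics`, `strain_days`, `strain`, `pairs`, `fit`,
#'   `derivatives`, `threshold`, `contrasts`, `log`.
#' @export
run_pipeline <- function(sensor, soil = NULL, meteo = NULL, trees = NULL,
                         out_dir = NULL, model = calibration_model(),
                         depth_cm = 100, k = 6, n_grid = 200, n_draws = 1000,
                         rwc_exclude = 0.95, completeness = 0.8,
                         n_perm = 5000, seed = 1L,
                         contrast_metrics = c("theta_turgid",
                                              "seasonal_delta",
                                              "diurnal_delta")) {
  if (inherits(sensor, "stem_scenario")) {
    sc <- sensor
    sensor <- sc$sensor; soil <- sc$soil; meteo <- sc$meteo; trees <- sc$trees
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  calibrated <- stage("calibrate", calibrate_series(sensor, model))
  days <- stage("summarise",
                summarise_days(calibrated, completeness = completeness))
  metrics <- stage("metrics",
                   storage_metrics(calibrated, days, trees = trees))
  vpd_daily <- if (!is.null(meteo))
    stage("meteorology", daily_max_vpd(meteo, completeness = completeness))
  strain_days <- stage("strain",
                       capacity_series(days, rwc_exclude = rwc_exclude))
  strain <- stage("strain", suppressWarnings(
    strain_thresholds(strain_days, vpd_daily = vpd_daily)))
  pairs <- fit <- derivs <- threshold <- NULL
  if (!is.null(soil)) {
    pairs <- stage("soil_coupling", daily_pairs(days, soil, depth_cm,
                                                trees = trees))
    fit <- stage("soil_coupling", fit_smooth(pairs, "pooled", k = k))
    derivs <- stage("soil_coupling",
                    derivative_with_ci(fit, n_grid = n_grid,
                                       n_draws = n_draws, seed = seed))
    threshold <- stage("soil_coupling", detect_threshold(derivs))
  }
  contrasts <- NULL
  if (!is.null(trees)) {
    contrasts <- stage("group_inference", dplyr::bind_rows(lapply(
      intersect(contrast_metrics, names(metrics)),
      function(m) group_contrast(metrics, m, n_perm = n_perm, seed = seed))))
  }
  log <- list(
    package_version = as.character(utils::packageVersion("stemwater")),
    r_version = R.version.string,
    seed = seed,
    settings = list(depth_cm = depth_cm, k = k, n_grid = n_grid,
                    n_draws = n_draws, rwc_exclude = rwc_exclude,
                    completeness = completeness, n_perm = n_perm,
                    calibration = unclass(model)),
    n_trees = length(unique(sensor$tree_id)),
    n_rows = nrow(sensor),
    timestamp_range = format(range(sensor$timestamp),
                             "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  out <- structure(list(calibrated = calibrated, days = days,
                        metrics = metrics, strain_days = strain_days,
                        strain = strain, pairs = pairs, fit = fit,
                        derivatives = derivs, threshold = threshold,
                        contrasts = contrasts, log = log),
                   class = "stem_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

write_pipeline <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_csv_iso(result$metrics, file.path(out_dir, "storage_metrics.csv"))
  write_csv_iso(result$days, file.path(out_dir, "daily_summaries.csv"))
  write_csv_iso(result$strain_days, file.path(out_dir, "strain_days.csv"))
  write_csv_iso(result$strain, file.path(out_dir, "strain_thresholds.csv"))
  if (!is.null(result$contrasts))
    write_csv_iso(result$contrasts, file.path(out_dir, "contrasts.csv"))
  if (!is.null(result$threshold)) {
    th <- result$threshold
    jsonlite::write_json(
      list(threshold_vwc = th$threshold_vwc,
           qualifying_run = th$qualifying_run,
           min_run = th$min_run,
           quartile_cutoff = th$quartile_cutoff,
           criteria = as.data.frame(th$criteria)),
      file.path(out_dir, "threshold.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    write_csv_iso(tibble::as_tibble(result$derivatives),
                  file.path(out_dir, "derivative_grid.csv"))
  }
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.stem_pipeline <- function(x, ...) {
  cat("<stem_pipeline>\n")
  cat(sprintf("  %d trees, %d days retained\n",
              nrow(x$metrics), nrow(x$days)))
  if (!is.null(x$threshold)) {
    if (is.na(x$threshold$threshold_vwc))
      cat("  soil threshold: none detected\n")
    else
      cat(sprintf("  soil threshold: %.3f m^3 m^-3\n",
                  x$threshold$threshold_vwc))
  }
  invisible(x)
}
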