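#' Percentile with the package-wide interpolation convention
#'
#' All percentile summaries in the package (seasonal 99th/1st, within-day
#' 99th/1st, the 99th percentile of daily ranges) use linear interpolation
#' between order statistics (`stats::quantile()` type 7), fixed here so every
#' stage agrees.
#'
#' @param values Numeric vector with at least one finite value; `NA` ignored.
#' @param p Percentile in \eqn{[0, 100]}.
#' @return The interpolated percentile.
#' @examples
#' percentile(1:100, 99) # 99.01
#' @export
percentile <- function(values, p) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values", call. = FALSE)
  stopifnot(p >= 0, p <= 100)
  stats::quantile(values, p / 100, type = 7, names = FALSE)
}

#' Daily hydration summaries per tree
#'
#' Collapses a calibrated 15-min (or other fixed-cadence) series to one row
#' per tree-day: the within-day 99th and 1st percentiles of water content, the
#' daily range (the day's discharge amplitude), and the daily maximum relative
#' water content `rwc_day_max = theta_day_hi / theta_turgid` — the night-time
#' hydration status proxy. Days with fewer than `completeness` of the expected
#' samples are excluded.
#'
#' @param calibrated Data frame with `tree_id`, `timestamp`, `theta` (e.g.
#'   from [calibrate_series()]).
#' @param theta_turgid Optional data frame `tree_id`, `theta_turgid` giving
#'   each tree's turgid reference; when `NULL` it is computed as the 99th
#'   percentile of that tree's full series.
#' @param completeness Minimum fraction of expected samples per day
#'   (default 0.8).
#' @param cadence_minutes Sampling interval; inferred when `NULL`.
#' @return A tibble `tree_id`, `date`, `theta_day_hi`, `theta_day_lo`,
#'   `daily_range`, `rwc_day_max`, `n_samples`.
#' @export
summarise_days <- function(calibrated, theta_turgid = NULL,
                           completeness = 0.8, cadence_minutes = NULL) {
  check_columns(calibrated, c("tree_id", "timestamp", "theta"), "calibrated")
  if (is.null(cadence_minutes))
    cadence_minutes <- infer_cadence(calibrated$timestamp)
  expected <- 1440 / cadence_minutes
  if (is.null(theta_turgid)) {
    theta_turgid <- calibrated |>
      dplyr::filter(is.finite(.data$theta)) |>
      dplyr::summarise(theta_turgid = percentile(.data$theta, 99),
                       .by = "tree_id")
  } else {
    check_columns(theta_turgid, c("tree_id", "theta_turgid"), "theta_turgid")
  }
  if (any(theta_turgid$theta_turgid <= 0))
    stop("theta_turgid must be positive", call. = FALSE)
  calibrated |>
    dplyr::filter(is.finite(.data$theta)) |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::summarise(
      theta_day_hi = percentile(.data$theta, 99),
      theta_day_lo = percentile(.data$theta, 1),
      n_samples = dplyr::n(),
      .by = c("tree_id", "date")) |>
    dplyr::filter(.data$n_samples >= completeness * expected) |>
    dplyr::mutate(daily_range = .data$theta_day_hi - .data$theta_day_lo) |>
    dplyr::left_join(theta_turgid, by = "tree_id") |>
    dplyr::mutate(rwc_day_max = .data$theta_day_hi / .data$theta_turgid) |>
    dplyr::select("tree_id", "date", "theta_day_hi", "theta_day_lo",
                  "daily_range", "rwc_day_max", "n_samples") |>
    dplyr::arrange(.data$tree_id, .data$date) |>
    tibble::as_tibble()
}

#' Per-tree storage statistics
#'
#' Computes, per tree, the seasonal storage summary: turgid water content
#' \eqn{\theta_t} (seasonal 99th percentile), dry water content \eqn{\theta_d}
#' (1st percentile), seasonal discharge magnitude
#' \eqn{\Delta\theta = \theta_t - \theta_d}, the maximum diurnal discharge
#' capacity (99th percentile of daily ranges), the water deficit
#' \eqn{(\theta_t - \theta_d)/\theta_t \times 100} (%), mean, SD and CV%.
#' When `trees` carries geometry (`group`, `height`, `dbh`, and
#' `sapwood_depth` for dicots), total active storage \eqn{S} in m\eqn{^3} is
#' added via [active_storage()] evaluated at \eqn{\theta_t}.
#'
#' @param calibrated Data frame `tree_id`, `timestamp`, `theta`.
#' @param days Daily summaries from [summarise_days()]; computed when `NULL`.
#' @param trees Optional tree metadata (`tree_id`, `group`, `height`, `dbh`,
#'   optionally `sapwood_depth`, `wood_density`).
#' @param p_hi,p_lo Percentiles defining \eqn{\theta_t} and \eqn{\theta_d}
#'   (defaults 99 and 1).
#' @return A tibble, one row per tree, with the columns above (plus `group`
#'   and `active_storage` when `trees` is given).
#' @examples
#' # a constant series has zero deltas and zero deficit
#' x <- tibble::tibble(tree_id = "t", theta = 0.5,
#'   timestamp = as.POSIXct("2023-07-01", tz = "UTC") + 900 * (0:191))
#' storage_metrics(x)
#' @export
storage_metrics <- function(calibrated, days = NULL, trees = NULL,
                            p_hi = 99, p_lo = 1) {
  check_columns(calibrated, c("tree_id", "timestamp", "theta"), "calibrated")
  if (!nrow(calibrated)) stop("empty series", call. = FALSE)
  if (is.null(days)) days <- summarise_days(calibrated)
  out <- calibrated |>
    dplyr::filter(is.finite(.data$theta)) |>
    dplyr::summarise(
      theta_turgid = percentile(.data$theta, p_hi),
      theta_dry = percentile(.data$theta, p_lo),
      theta_mean = mean(.data$theta),
      theta_sd = stats::sd(.data$theta),
      .by = "tree_id") |>
    dplyr::mutate(
      cv_pct = 100 * .data$theta_sd / .data$theta_mean,
      seasonal_delta = .data$theta_turgid - .data$theta_dry,
      water_deficit_pct = 100 * .data$seasonal_delta / .data$theta_turgid) |>
    dplyr::left_join(
      days |> dplyr::summarise(
        diurnal_delta = percentile(.data$daily_range, 99), .by = "tree_id"),
      by = "tree_id")
  if (!is.null(trees)) {
    check_columns(trees, c("tree_id", "group", "height", "dbh"), "trees")
    out <- out |>
      dplyr::left_join(trees, by = "tree_id") |>
      dplyr::mutate(active_storage = active_storage(
        .data$group, .data$height, .data$dbh, .data$theta_turgid,
        sapwood_depth = if ("sapwood_depth" %in% names(trees))
          .data$sapwood_depth else NULL))
  }
  tibble::as_tibble(out)
}

#' Sapwood cross-sectional area
#'
#' Annulus between the stem perimeter and the heartwood boundary:
#' \eqn{A_s = \pi[(DBH/2)^2 - (DBH/2 - d_s)^2]}.
#'
#' @param dbh Diameter at breast height, m.
#' @param sapwood_depth Radial sapwood depth, m; must be below `dbh / 2`.
#' @return Sapwood area, m\eqn{^2}.
#' @examples
#' sapwood_area(0.22, 0.035) # about 0.02034
#' @export
sapwood_area <- function(dbh, sapwood_depth) {
  if (any(dbh <= 0, na.rm = TRUE) || any(sapwood_depth <= 0, na.rm = TRUE))
    stop("dbh and sapwood_depth must be positive", call. = FALSE)
  if (any(sapwood_depth >= dbh / 2, na.rm = TRUE))
    stop("sapwood_depth must be smaller than the stem radius; ",
         "use whole-stem geometry instead", call. = FALSE)
  r <- dbh / 2
  pi * (r^2 - (r - sapwood_depth)^2)
}

#' Total active stem water storage
#'
#' Volume of physiologically active stored water, \eqn{S = V \cdot \theta}.
#' Palms conduct and store through the whole stem and are treated as perfect
#' cylinders, \eqn{V = \pi (DBH/2)^2 H}. Dicots store active water in the
#' sapwood only; the tapered sapwood volume is \eqn{V_s = f A_s H} with
#' tapering factor \eqn{f} (default 0.5) and the sapwood annulus area
#' \eqn{A_s} from [sapwood_area()].
#'
#' @param group `"palm"` or `"dicot"`, vectorised with the geometry.
#' @param height Tree height, m.
#' @param dbh Diameter at breast height, m.
#' @param theta Volumetric water content to evaluate the storage at
#'   (typically \eqn{\theta_t}), m\eqn{^3} m\eqn{^{-3}}.
#' @param sapwood_depth Sapwood depth, m; required for dicots. When `NULL`,
#'   [sapwood_depth_allometry()] is used.
#' @param taper Tapering factor for the dicot sapwood volume.
#' @return Active storage, m\eqn{^3}.
#' @examples
#' active_storage("palm", height = 13, dbh = 0.22, theta = 0.728) # ~0.36 m^3
#' @export
active_storage <- function(group, height, dbh, theta,
                           sapwood_depth = NULL, taper = 0.5) {
  group <- match_group(group)
  if (any(is.na(height) | height <= 0) || any(is.na(dbh) | dbh <= 0))
    stop("height and dbh must be positive for every tree", call. = FALSE)
  if (is.null(sapwood_depth))
    sapwood_depth <- sapwood_depth_allometry(dbh)
  sapwood_depth <- ifelse(is.na(sapwood_depth) & group == "dicot",
                          sapwood_depth_allometry(dbh), sapwood_depth)
  n <- max(length(group), length(height), length(dbh), length(theta))
  group <- rep_len(group, n); height <- rep_len(height, n)
  dbh <- rep_len(dbh, n); theta <- rep_len(theta, n)
  sapwood_depth <- rep_len(sapwood_depth, n)
  vol <- ifelse(group == "palm",
                pi * (dbh / 2)^2 * height,
                taper * sapwood_area_safe(dbh, sapwood_depth) * height)
  vol * theta
}

# vectorised annulus that tolerates palm rows carrying NA depth
sapwood_area_safe <- function(dbh, depth) {
  if (any(depth >= dbh / 2, na.rm = TRUE))
    stop("sapwood_depth must be smaller than the stem radius", call. = FALSE)
  pi * ((dbh / 2)^2 - (dbh / 2 - depth)^2)
}

match_group <- function(group) {
  g <- tolower(as.character(group))
  bad <- !g %in% c("palm", "dicot")
  if (any(bad))
    stop("`group` must be \"palm\" or \"dicot\" (got: ",
         paste(unique(group[bad]), collapse = ", "), ")", call. = FALSE)
  g
}

#' Linear DBH-to-sapwood-depth allometry
#'
#' Fallback used when a dicot's sapwood depth was not measured. The
#' relationship is linear through the origin, anchored by default at 3.5 cm
#' depth for a 0.22 m DBH subcanopy tree; both coefficients are overridable
#' when a site-specific allometry is available.
#'
#' @param dbh Diameter at breast height, m.
#' @param slope Depth gained per unit DBH (default `0.035 / 0.22`).
#' @param intercept Depth at zero DBH, m (default 0).
#' @return Sapwood depth, m.
#' @export
sapwood_depth_allometry <- function(dbh, slope = 0.035 / 0.22, intercept = 0) {
  intercept + slope * dbh
}

#' Relative soil water content
#'
#' Normalises volumetric soil water content by a long-term reference maximum
#' (the 99th percentile of the long-term record), giving a dimensionless soil
#' RWC comparable across depths and sites.
#'
#' @param vwc Soil volumetric water content, m\eqn{^3} m\eqn{^{-3}}.
#' @param reference_max Long-term 99th-percentile VWC, > 0.
#' @return Dimensionless soil relative water content.
#' @export
relative_soil_water <- function(vwc, reference_max) {
  if (!is.numeric(reference_max) || any(reference_max <= 0, na.rm = TRUE))
    stop("reference_max must be positive", call. = FALSE)
  vwc / reference_max
}
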