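#' Daily relative discharge capacity and strain class
#'
#' Expresses each day's stem water discharge amplitude as a percentage of the
#' tree's maximum diurnal discharge capacity (its 99th-percentile daily
#' range), and classifies each day's hydraulic strain. Days with
#' `rwc_day_max` above the exclusion cutoff (default 0.95) are marked
#' `excluded`: at high hydration a small amplitude reflects water abundance,
#' not hydraulic limitation, so such days carry no strain information.
#'
#' @param days Daily summaries from [summarise_days()] (per tree).
#' @param diurnal_delta_max Optional data frame `tree_id`, `diurnal_delta`
#'   giving each tree's maximum diurnal discharge capacity
#'   (m\eqn{^3} m\eqn{^{-3}}); computed as the 99th percentile of
#'   `daily_range` per tree when `NULL`.
#' @param rwc_exclude Daily-max RWC above which a day is excluded from strain
#'   statistics (default 0.95).
#' @return A tibble `tree_id`, `date`, `rwc_day_max`, `capacity_pct`,
#'   `strain_class` (factor: none, moderate, high, severe, excluded).
#' @export
capacity_series <- function(days, diurnal_delta_max = NULL,
                            rwc_exclude = 0.95) {
  check_columns(days, c("tree_id", "date", "daily_range", "rwc_day_max"),
                "days")
  if (is.null(diurnal_delta_max)) {
    diurnal_delta_max <- days |>
      dplyr::summarise(diurnal_delta = percentile(.data$daily_range, 99),
                       .by = "tree_id")
  } else {
    check_columns(diurnal_delta_max, c("tree_id", "diurnal_delta"),
                  "diurnal_delta_max")
  }
  if (any(diurnal_delta_max$diurnal_delta <= 0))
    stop("diurnal_delta must be positive (degenerate tree with no ",
         "diurnal signal)", call. = FALSE)
  days |>
    dplyr::left_join(diurnal_delta_max, by = "tree_id") |>
    dplyr::mutate(
      capacity_pct = 100 * .data$daily_range / .data$diurnal_delta,
      strain_class = dplyr::if_else(
        .data$rwc_day_max > rwc_exclude, "excluded",
        as.character(classify_strain(.data$capacity_pct))),
      strain_class = factor(.data$strain_class, levels = strain_levels())) |>
    dplyr::select("tree_id", "date", "rwc_day_max", "capacity_pct",
                  "strain_class") |>
    tibble::as_tibble()
}

strain_levels <- function() c("none", "moderate", "high", "severe", "excluded")

#' Classify hydraulic strain from discharge capacity
#'
#' Bins the daily relative discharge capacity into hydraulic-strain classes:
#' severe below 5% of maximum capacity, high in \eqn{[5, 10)}%, moderate in
#' \eqn{[10, 20)}%, none at 20% and above. Bins are lower-inclusive; exact
#' boundary hits are measure-zero on real data.
#'
#' @param capacity_pct Daily discharge capacity, percent of maximum; >= 0.
#' @return Factor with levels none, moderate, high, severe.
#' @examples
#' classify_strain(c(3, 7, 12, 50))
#' @export
classify_strain <- function(capacity_pct) {
  if (any(capacity_pct < 0, na.rm = TRUE))
    stop("capacity_pct must be non-negative", call. = FALSE)
  cls <- dplyr::case_when(
    capacity_pct < 5 ~ "severe",
    capacity_pct < 10 ~ "high",
    capacity_pct < 20 ~ "moderate",
    .default = "none")
  factor(cls, levels = c("none", "moderate", "high", "severe"))
}

#' Critical relative water content thresholds per tree
#'
#' Derives, per tree, the hydraulic-strain summary:
#' \describe{
#'   \item{rwc_crit}{mean (with SD) of daily-max RWC over non-excluded days
#'     whose discharge capacity fell below 10% of maximum — the hydration
#'     level at which diurnal water mobilisation is critically impaired. When
#'     no day dropped below 10%, the threshold was never reached and is
#'     reported as a censored upper bound at the minimum observed daily-max
#'     RWC (`rwc_crit_censored = TRUE`, label `"< x"`).}
#'   \item{rwc_mrc}{mean (with SD) of daily-max RWC over days with capacity
#'     above 75% of maximum, computed over the entire record including
#'     high-hydration days — near-optimal hydraulic functioning.}
#'   \item{d_crit_10, d_crit_5, d_mod}{counts of non-excluded days below 10%
#'     capacity, below 5%, and in the moderate class \eqn{[10, 20)}%.}
#' }
#'
#' @param strain_days Output of [capacity_series()].
#' @param vpd_daily Optional per-day maximum VPD (`date`, `vpd_max`) to add
#'   the stress-day VPD-capacity Pearson correlation
#'   (see [vpd_capacity_correlation()]).
#' @return A tibble, one row per tree: `rwc_crit`, `rwc_crit_sd`,
#'   `rwc_crit_censored`, `rwc_crit_label`, `rwc_mrc`, `rwc_mrc_sd`,
#'   `rwc_min`, `d_crit_10`, `d_crit_5`, `d_mod`, and `vpd_capacity_r` when
#'   `vpd_daily` is supplied.
#' @export
strain_thresholds <- function(strain_days, vpd_daily = NULL) {
  check_columns(strain_days,
                c("tree_id", "date", "rwc_day_max", "capacity_pct",
                  "strain_class"), "strain_days")
  if (!nrow(strain_days)) stop("no strain days", call. = FALSE)
  out <- strain_days |>
    dplyr::summarise(
      rwc_crit = mean_or_na(.data$rwc_day_max[.data$strain_class != "excluded" &
                                                .data$capacity_pct < 10]),
      rwc_crit_sd = sd_or_na(.data$rwc_day_max[.data$strain_class != "excluded" &
                                                 .data$capacity_pct < 10]),
      rwc_mrc = mean_or_na(.data$rwc_day_max[.data$capacity_pct > 75]),
      rwc_mrc_sd = sd_or_na(.data$rwc_day_max[.data$capacity_pct > 75]),
      rwc_min = min(.data$rwc_day_max),
      d_crit_10 = sum(.data$strain_class != "excluded" &
                        .data$capacity_pct < 10),
      d_crit_5 = sum(.data$strain_class != "excluded" &
                       .data$capacity_pct < 5),
      d_mod = sum(.data$strain_class == "moderate"),
      .by = "tree_id") |>
    dplyr::mutate(
      rwc_crit_censored = .data$d_crit_10 == 0,
      rwc_crit_label = dplyr::if_else(
        .data$rwc_crit_censored,
        sprintf("< %.2f", .data$rwc_min),
        sprintf("%.2f", .data$rwc_crit)),
      .after = "rwc_crit_sd")
  if (any(is.na(out$rwc_mrc)))
    warning("rwc_mrc undefined for tree(s) with no day above 75% capacity: ",
            paste(out$tree_id[is.na(out$rwc_mrc)], collapse = ", "),
            call. = FALSE)
  if (!is.null(vpd_daily)) {
    out <- dplyr::left_join(
      out, vpd_capacity_correlation(strain_days, vpd_daily), by = "tree_id")
  }
  tibble::as_tibble(out)
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_

#' Pearson correlation between daily maximum VPD and discharge capacity
#'
#' Computed over stress days only (daily-max RWC at or below the exclusion
#' cutoff): a strong positive correlation would mean the reduced discharge
#' tracks atmospheric demand, while a weak or negative one points to internal
#' regulation (stomatal closure) controlling discharge during drought.
#'
#' @param strain_days Output of [capacity_series()].
#' @param vpd_daily Per-day maximum VPD: columns `date`, `vpd_max`
#'   (see [daily_max_vpd()]).
#' @param min_days Minimum paired stress days required (default 3).
#' @return A tibble `tree_id`, `vpd_capacity_r`, `n_stress_days`; `r` is `NA`
#'   (with a warning) for trees with too few stress days or zero variance.
#' @export
vpd_capacity_correlation <- function(strain_days, vpd_daily, min_days = 3) {
  check_columns(vpd_daily, c("date", "vpd_max"), "vpd_daily")
  out <- strain_days |>
    dplyr::filter(.data$strain_class != "excluded") |>
    dplyr::inner_join(vpd_daily, by = "date") |>
    dplyr::summarise(
      vpd_capacity_r = if (dplyr::n() >= min_days &&
                           stats::sd(.data$capacity_pct) > 0 &&
                           stats::sd(.data$vpd_max) > 0)
        stats::cor(.data$vpd_max, .data$capacity_pct) else NA_real_,
      n_stress_days = dplyr::n(),
      .by = "tree_id")
  if (any(is.na(out$vpd_capacity_r)))
    warning("VPD-capacity correlation undefined for tree(s): ",
            paste(out$tree_id[is.na(out$vpd_capacity_r)], collapse = ", "),
            call. = FALSE)
  tibble::as_tibble(out)
}
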