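#' Pair daily maximum soil moisture with daily maximum stem RWC
#'
#' Joins, on calendar date, the per-day maximum soil volumetric water content
#' at one depth with each tree's daily maximum stem relative water content.
#' Days missing either side are dropped.
#'
#' @param stem_days Daily summaries from [summarise_days()].
#' @param soil Long-format soil series: `timestamp`, `depth_cm`, `vwc`.
#' @param depth_cm Soil depth to use (default 100 cm, the headline depth).
#' @param trees Optional tree metadata (`tree_id`, `group`) to attach the
#'   plant-type label.
#' @return A tibble `date`, `soil_vwc` (daily max), `stem_rwc`
#'   (`rwc_day_max`), `tree_id`, and `group` when `trees` is given.
#' @export
daily_pairs <- function(stem_days, soil, depth_cm = 100, trees = NULL) {
  check_columns(stem_days, c("tree_id", "date", "rwc_day_max"), "stem_days")
  check_columns(soil, c("timestamp", "depth_cm", "vwc"), "soil")
  soil_sub <- dplyr::filter(soil, .data$depth_cm == !!depth_cm,
                            is.finite(.data$vwc))
  if (!nrow(soil_sub))
    stop(sprintf("no soil data at depth %s cm", depth_cm), call. = FALSE)
  soil_daily <- soil_sub |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::summarise(soil_vwc = max(.data$vwc), .by = "date")
  pairs <- stem_days |>
    dplyr::inner_join(soil_daily, by = "date") |>
    dplyr::transmute(date = .data$date, soil_vwc = .data$soil_vwc,
                     stem_rwc = .data$rwc_day_max, tree_id = .data$tree_id)
  if (!nrow(pairs))
    stop("stem and soil series do not overlap in time", call. = FALSE)
  if (!is.null(trees)) {
    check_columns(trees, c("tree_id", "group"), "trees")
    pairs <- dplyr::left_join(
      pairs, dplyr::select(trees, "tree_id", "group"), by = "tree_id")
  }
  tibble::as_tibble(pairs)
}

#' Fit a penalized-spline soil-to-stem response curve
#'
#' Fits stem RWC as a smooth function of soil VWC with a penalized cubic
#' regression spline (basis dimension `k`, default 6), smoothing parameter
#' selected by REML, Gaussian response. This is the smooth whose first
#' derivative drives [detect_threshold()]. If REML fails to converge the fit
#' falls back to GCV with a warning.
#'
#' @param pairs Output of [daily_pairs()]; when `group` is not `"pooled"`,
#'   only rows of that plant type are used.
#' @param group `"pooled"` (default), `"palm"` or `"dicot"`.
#' @param k Spline basis dimension (>= 3).
#' @return An object of class `soil_smooth` wrapping the `mgcv::gam` fit,
#'   with `tidy()`, `glance()`, `augment()` and `autoplot()` methods.
#' @export
fit_smooth <- function(pairs, group = c("pooled", "palm", "dicot"), k = 6) {
  group <- match.arg(group)
  check_columns(pairs, c("soil_vwc", "stem_rwc"), "pairs")
  if (group != "pooled") {
    check_columns(pairs, "group", "pairs")
    pairs <- dplyr::filter(pairs, .data$group == !!group)
  }
  if (k < 3) stop("basis dimension k must be at least 3", call. = FALSE)
  if (length(unique(pairs$soil_vwc)) < k)
    stop(sprintf("need at least k = %d distinct soil VWC values", k),
         call. = FALSE)
  dat <- data.frame(x = pairs$soil_vwc, y = pairs$stem_rwc)
  fit <- tryCatch(
    mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat, method = "REML"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("REML smoothing selection did not converge; falling back to GCV",
            call. = FALSE)
    fit <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat,
                     method = "GCV.Cp")
  }
  structure(list(gam = fit, group = group, k = k,
                 x_range = range(dat$x), n = nrow(dat)),
            class = "soil_smooth")
}

#' @export
print.soil_smooth <- function(x, ...) {
  g <- summary(x$gam)
  cat(sprintf("<soil_smooth> %s fit, k = %d, n = %d\n", x$group, x$k, x$n))
  cat(sprintf("  soil VWC range [%.3f, %.3f] m^3 m^-3\n",
              x$x_range[1], x$x_range[2]))
  cat(sprintf("  edf = %.2f, R^2(adj) = %.3f, smoothing parameter = %.3g\n",
              sum(x$gam$edf), g$r.sq, x$gam$sp[1]))
  invisible(x)
}

#' First derivative of the fitted response with simulation CIs
#'
#' Evaluates the derivative of the fitted smooth, d(stem RWC)/d(soil VWC), on
#' a uniform grid over the observed soil range. The derivative is exact for
#' the cubic spline basis up to a centred difference at step
#' \eqn{10^{-6}} of the range; pointwise confidence intervals come from
#' simulating coefficient vectors from the Gaussian approximation to their
#' posterior (`n_draws`, seeded for reproducibility).
#'
#' @param fit A `soil_smooth` from [fit_smooth()].
#' @param n_grid Number of grid points (default 200).
#' @param n_draws Posterior draws for the CI (default 1000).
#' @param seed Integer seed for the draws.
#' @param level Confidence level (default 0.95).
#' @return An object of class `deriv_grid`: a tibble `soil_vwc`,
#'   `derivative`, `ci_lower`, `ci_upper`, `fitted`.
#' @export
derivative_with_ci <- function(fit, n_grid = 200, n_draws = 1000,
                               seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "soil_smooth"))
  grid <- seq(fit$x_range[1], fit$x_range[2], length.out = n_grid)
  h <- diff(fit$x_range) * 1e-6
  Xf <- stats::predict(fit$gam, data.frame(x = grid + h), type = "lpmatrix")
  Xb <- stats::predict(fit$gam, data.frame(x = grid - h), type = "lpmatrix")
  Xd <- (Xf - Xb) / (2 * h)
  beta <- stats::coef(fit$gam)
  deriv <- drop(Xd %*% beta)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  draws <- rmvn_chol(n_draws, beta, fit$gam$Vp)
  dmat <- Xd %*% t(draws)                        # n_grid x n_draws
  alpha <- (1 - level) / 2
  ci <- t(apply(dmat, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  out <- tibble::tibble(
    soil_vwc = grid,
    derivative = unname(deriv),
    ci_lower = unname(ci[, 1]),
    ci_upper = unname(ci[, 2]),
    fitted = as.numeric(stats::predict(fit$gam, data.frame(x = grid))))
  structure(out, class = c("deriv_grid", class(out)))
}

# multivariate normal draws via Cholesky (with a tiny ridge for safety)
rmvn_chol <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma),
                 error = function(e) chol(sigma + diag(1e-10, p)))
  matrix(stats::rnorm(n * p), n, p) %*% ch +
    matrix(mu, n, p, byrow = TRUE)
}

#' Detect the sustained rapid-decline soil-moisture threshold
#'
#' Applies the breakpoint rule to a derivative grid, working in the
#' \emph{drying direction}: the decline of stem RWC as the soil dries is the
#' negated VWC-direction derivative, \eqn{D = -\,d\hat\theta/dVWC}, so a
#' rapid stem-water decline is a strongly negative \eqn{D}. A grid point
#' qualifies when the decline is significant (the upper confidence limit of
#' \eqn{D} below zero, i.e. the VWC-direction derivative significantly
#' positive) \emph{and} pronounced (\eqn{D} within the strongest negative
#' quartile — at or below the 25th percentile of all grid values of
#' \eqn{D}). Scanning from wet toward dry soil, the threshold is the soil
#' VWC of the first point opening a run of at least `min_run` consecutive
#' qualifying points — the entry into the sustained rapid-decline zone.
#' Absence of such a run is a valid result (`threshold_vwc = NA`).
#'
#' @param deriv A `deriv_grid` from [derivative_with_ci()] (derivatives in
#'   the VWC direction; the negation happens here).
#' @param min_run Minimum run length of qualifying points (default 5).
#' @return An object of class `soil_threshold`: a list with `threshold_vwc`,
#'   `qualifying_run` (grid index range in wet-to-dry order, or `NULL`),
#'   `quartile_cutoff` (on the drying-direction scale), and `criteria` (the
#'   per-point trace: `soil_vwc`, `drying_derivative`, `drying_ci_upper`,
#'   `significant`, `strong_quartile`, `qualifying`, `in_run`, plus the
#'   original columns).
#' @export
detect_threshold <- function(deriv, min_run = 5) {
  check_columns(deriv, c("soil_vwc", "derivative", "ci_lower", "ci_upper"),
                "deriv")
  g <- dplyr::arrange(tibble::as_tibble(deriv),
                      dplyr::desc(.data$soil_vwc))    # wet -> dry
  g$drying_derivative <- -g$derivative
  g$drying_ci_upper <- -g$ci_lower
  q25 <- percentile(g$drying_derivative, 25)
  g <- g |>
    dplyr::mutate(
      significant = .data$drying_ci_upper < 0,
      strong_quartile = .data$drying_derivative <= q25,
      qualifying = .data$significant & .data$strong_quartile)
  r <- rle(g$qualifying)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit)) {
    run <- c(starts[hit[1]], ends[hit[1]])
    thr <- g$soil_vwc[run[1]]
  } else {
    run <- NULL
    thr <- NA_real_
  }
  g$in_run <- FALSE
  if (!is.null(run)) g$in_run[run[1]:run[2]] <- TRUE
  structure(list(threshold_vwc = thr, qualifying_run = run,
                 min_run = min_run, quartile_cutoff = q25, criteria = g),
            class = "soil_threshold")
}

#' @export
print.soil_threshold <- function(x, ...) {
  cat("<soil_threshold>\n")
  if (is.na(x$threshold_vwc)) {
    cat(sprintf("  no sustained decline (no run of >= %d qualifying points)\n",
                x$min_run))
  } else {
    cat(sprintf("  threshold at soil VWC %.3f m^3 m^-3 ", x$threshold_vwc))
    cat(sprintf("(run of %d qualifying points)\n",
                x$qualifying_run[2] - x$qualifying_run[1] + 1))
  }
  invisible(x)
}

#' Compare pooled vs plant-type-specific response curves
#'
#' Model comparison (F test) of a single pooled smooth against a model with a
#' separate smooth per plant type, answering whether palms and dicots differ
#' in their soil-to-stem response curve shape.
#'
#' @param pairs Output of [daily_pairs()] with a `group` column.
#' @param k Basis dimension for every smooth (default 6).
#' @return A one-row tibble `df`, `deviance`, `f_statistic`, `p_value`,
#'   `r_sq_pooled`, `r_sq_by_group`.
#' @export
compare_groups <- function(pairs, k = 6) {
  check_columns(pairs, c("soil_vwc", "stem_rwc", "group"), "pairs")
  if (length(unique(pairs$group)) < 2)
    stop("need both plant types to compare response curves", call. = FALSE)
  dat <- data.frame(x = pairs$soil_vwc, y = pairs$stem_rwc,
                    group = factor(pairs$group))
  m0 <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat, method = "REML")
  m1 <- mgcv::gam(y ~ group + s(x, by = group, k = k, bs = "cr"),
                  data = dat, method = "REML")
  a <- stats::anova(m0, m1, test = "F")
  tibble::tibble(
    df = a$Df[2],
    deviance = a$Deviance[2],
    f_statistic = a$F[2],
    p_value = a$`Pr(>F)`[2],
    r_sq_pooled = summary(m0)$r.sq,
    r_sq_by_group = summary(m1)$r.sq)
}
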