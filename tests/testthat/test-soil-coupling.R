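soil_axis <- function(n_days, vwc_fun) {
  ts <- as.POSIXct("2023-07-01", tz = "UTC") + 3600 * (seq_len(n_days * 24) - 1)
  d <- floor(as.numeric(ts - ts[1]) / 86400) + 1
  tibble::tibble(timestamp = ts, depth_cm = 100, vwc = vwc_fun(d))
}

test_that("daily_pairs joins stem and soil by calendar date", {
  days <- tibble::tibble(tree_id = "t1", date = as.Date("2023-07-01"),
                         rwc_day_max = 0.9)
  soil <- soil_axis(1, function(d) 0.25)
  p <- daily_pairs(days, soil)
  expect_equal(nrow(p), 1)
  expect_equal(p$soil_vwc, 0.25)
  expect_equal(p$stem_rwc, 0.9)

  # stem day without soil data is dropped
  days2 <- tibble::tibble(tree_id = "t1",
                          date = as.Date(c("2023-07-01", "2023-09-01")),
                          rwc_day_max = c(0.9, 0.8))
  expect_equal(nrow(daily_pairs(days2, soil)), 1)

  # no overlap at all is an error
  days3 <- tibble::tibble(tree_id = "t1", date = as.Date("2024-01-01"),
                          rwc_day_max = 0.9)
  expect_error(daily_pairs(days3, soil), "overlap")
  expect_error(daily_pairs(days, soil, depth_cm = 250), "250")
})

test_that("pair count is bounded by days x trees on a full scenario", {
  sc <- generate_scenario(short_config(n_days = 12, seed = 3))
  cal <- calibrate_series(sc$sensor)
  days <- summarise_days(cal)
  p <- daily_pairs(days, sc$soil, trees = sc$trees)
  expect_lte(nrow(p), 12 * 7)
  expect_true(all(c("palm", "dicot") %in% p$group))
})

test_that("penalized spline shrinks to a line and tracks a sine", {
  set.seed(1)
  x <- seq(0, 1, length.out = 120)
  lin <- tibble::tibble(soil_vwc = x, stem_rwc = 0.2 + 0.5 * x +
                          rnorm(120, sd = 1e-4))
  f <- fit_smooth(lin)
  expect_s3_class(f, "soil_smooth")
  expect_lt(max(abs(augment(f)$.resid)), 1e-3)
  expect_lt(glance(f)$edf - 2, 1.5)     # near-linear effective df

  sine <- tibble::tibble(soil_vwc = x, stem_rwc = sin(2 * pi * x))
  fs <- fit_smooth(sine, k = 6)
  rmse <- sqrt(mean(augment(fs)$.resid^2))
  expect_lt(rmse, 0.25)                 # rmse well below unit amplitude

  # too few distinct x values
  dup <- tibble::tibble(soil_vwc = rep(c(0.1, 0.2, 0.3), 10),
                        stem_rwc = runif(30))
  expect_error(fit_smooth(dup, k = 6), "distinct")
})

test_that("derivative grid matches a linear fit's slope and is seeded", {
  set.seed(2)
  x <- runif(200, 0.1, 0.4)
  pairs <- tibble::tibble(soil_vwc = x, stem_rwc = 1.5 * x + rnorm(200, sd = 1e-3))
  f <- fit_smooth(pairs)
  d1 <- derivative_with_ci(f, n_grid = 50, n_draws = 300, seed = 9)
  expect_equal(d1$derivative, rep(1.5, 50), tolerance = 0.02)
  expect_true(all(d1$ci_lower <= d1$derivative & d1$derivative <= d1$ci_upper))
  d2 <- derivative_with_ci(f, n_grid = 50, n_draws = 300, seed = 9)
  expect_identical(d1, d2)
})

test_that("derivative integrates back to the fitted curve", {
  sc <- generate_scenario(short_config(n_days = 20, seed = 8))
  cal <- calibrate_series(sc$sensor)
  p <- daily_pairs(summarise_days(cal), sc$soil)
  f <- fit_smooth(p)
  g <- derivative_with_ci(f, n_grid = 2001, n_draws = 10, seed = 1)
  dx <- diff(g$soil_vwc)
  integral <- cumsum(c(0, (g$derivative[-1] + g$derivative[-2001]) / 2 * dx))
  reconstructed <- g$fitted[1] + integral
  scale <- diff(range(g$fitted))
  if (scale == 0) scale <- 1
  expect_lt(max(abs(reconstructed - g$fitted)) / scale, 1e-6)
})

test_that("threshold rule is applied verbatim on constructed grids", {
  vwc <- seq(0.30, 0.15, by = -0.01)            # 16 points, wet -> dry
  # all positive drying derivatives: nothing declines, no threshold
  th <- detect_threshold(make_deriv_grid(vwc, drying = rep(2, 16)))
  expect_true(is.na(th$threshold_vwc))

  # one qualifying 5-point run starting exactly at 0.19
  drying <- rep(0.5, 16)
  drying[vwc <= 0.19 + 1e-9] <- -8              # 0.19 .. 0.15
  th2 <- detect_threshold(make_deriv_grid(vwc, drying))
  expect_equal(th2$threshold_vwc, 0.19)
  tr <- tidy(th2)
  expect_equal(sum(tr$qualifying), 5)
  expect_equal(sum(tr$in_run), 5)

  # a 4-point run does not qualify
  drying4 <- rep(0.5, 16)
  drying4[vwc <= 0.18 + 1e-9] <- -8             # 0.18 .. 0.15: 4 points
  th3 <- detect_threshold(make_deriv_grid(vwc, drying4))
  expect_true(is.na(th3$threshold_vwc))

  # significance and quartile must BOTH hold: strong decline with wide CI
  g <- make_deriv_grid(vwc, drying, half_width = 20)
  expect_true(is.na(detect_threshold(g)$threshold_vwc))
})

test_that("threshold detection is invariant to affine response rescaling", {
  vwc <- seq(0.32, 0.15, length.out = 40)
  drying <- -2 / (1 + exp((vwc - 0.19) / 0.004))   # smooth knee at 0.19
  g <- make_deriv_grid(vwc, drying, half_width = 0.05)
  th <- detect_threshold(g)
  g2 <- g
  b <- 3.7                                         # y -> a + b*y scales d/dx by b
  g2$derivative <- b * g2$derivative
  g2$ci_lower <- b * g2$ci_lower
  g2$ci_upper <- b * g2$ci_upper
  th2 <- detect_threshold(g2)
  expect_equal(th$threshold_vwc, th2$threshold_vwc)
  expect_equal(tidy(th)$qualifying, tidy(th2)$qualifying)
})

test_that("group comparison separates different knees and not a shared curve", {
  set.seed(31)
  n <- 150
  x <- runif(n, 0.15, 0.32)
  shared <- function(x) 1 / (1 + exp(-(x - 0.19) / 0.01))
  pairs_null <- tibble::tibble(
    soil_vwc = rep(x, 2),
    stem_rwc = shared(rep(x, 2)) + rnorm(2 * n, sd = 0.02),
    group = rep(c("palm", "dicot"), each = n))
  null_res <- compare_groups(pairs_null)
  expect_gt(null_res$p_value, 0.05)

  strong <- function(x) 1 / (1 + exp(-(x - 0.26) / 0.01))
  pairs_alt <- tibble::tibble(
    soil_vwc = rep(x, 2),
    stem_rwc = c(shared(x), strong(x)) + rnorm(2 * n, sd = 0.02),
    group = rep(c("palm", "dicot"), each = n))
  alt_res <- compare_groups(pairs_alt)
  expect_lt(alt_res$p_value, 1e-6)

  # identical data in both groups: statistic near zero
  pairs_same <- tibble::tibble(
    soil_vwc = rep(x, 2), stem_rwc = rep(shared(x), 2),
    group = rep(c("palm", "dicot"), each = n))
  same_res <- compare_groups(pairs_same)
  expect_lt(abs(same_res$deviance), 1e-4)
  expect_error(compare_groups(pairs_null[pairs_null$group == "palm", ]),
               "both plant types")
})
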