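test_that("capacity is the daily range relative to the tree maximum", {
  sdays <- make_strain_days(c(100, 50), rwc = c(0.9, 0.9))
  expect_equal(sdays$capacity_pct, c(100, 50))
  # high-hydration days are excluded regardless of capacity
  sdays <- make_strain_days(c(3, 40), rwc = c(0.97, 0.99))
  expect_equal(as.character(sdays$strain_class), c("excluded", "excluded"))
  # degenerate tree
  days <- tibble::tibble(tree_id = "t", date = as.Date("2023-07-01"),
                         daily_range = 0, rwc_day_max = 0.9)
  expect_error(
    capacity_series(days, tibble::tibble(tree_id = "t", diurnal_delta = 0)),
    "positive")
})

test_that("strain classes partition capacity with lower-inclusive bins", {
  expect_equal(as.character(classify_strain(c(3, 12, 50))),
               c("severe", "moderate", "none"))
  expect_equal(as.character(classify_strain(c(0, 4.999, 5, 9.999, 10,
                                              19.999, 20, 1e6))),
               c("severe", "severe", "high", "high", "moderate",
                 "moderate", "none", "none"))
  # exactly one class everywhere on [0, inf)
  x <- c(runif(200, 0, 30), runif(50, 30, 500))
  expect_false(anyNA(classify_strain(x)))
  expect_error(classify_strain(-1), "non-negative")
})

test_that("strain thresholds follow the stated rules on a hand case", {
  sdays <- make_strain_days(c(4, 6, 9, 15), rwc = c(0.60, 0.65, 0.70, 0.80))
  res <- suppressWarnings(strain_thresholds(sdays))   # no day above 75%
  expect_equal(res$rwc_crit, 0.65)
  expect_equal(res$rwc_crit_sd, sd(c(0.60, 0.65, 0.70)))
  expect_equal(res$d_crit_10, 3L)
  expect_equal(res$d_crit_5, 1L)
  expect_equal(res$d_mod, 1L)
  expect_false(res$rwc_crit_censored)
  expect_equal(res$rwc_min, 0.60)
  expect_true(res$d_crit_5 <= res$d_crit_10)
})

test_that("rwc_crit is censored at the minimum daily-max RWC when unreached", {
  sdays <- make_strain_days(c(40, 80, 95), rwc = c(0.73, 0.85, 0.99))
  res <- suppressWarnings(strain_thresholds(sdays))
  expect_true(res$rwc_crit_censored)
  expect_true(is.na(res$rwc_crit))
  expect_equal(res$rwc_crit_label, "< 0.73")
  expect_equal(res$d_crit_10, 0L)
})

test_that("rwc_mrc uses the entire record including high hydration days", {
  sdays <- make_strain_days(c(100, 90, 80, 8), rwc = c(1.0, 0.97, 0.9, 0.7))
  res <- strain_thresholds(sdays)
  expect_equal(res$rwc_mrc, mean(c(1.0, 0.97, 0.9)))
  # all days at full capacity: mrc defined, no strain days
  sdays2 <- make_strain_days(rep(100, 4), rwc = rep(1, 4))
  res2 <- suppressWarnings(strain_thresholds(sdays2))
  expect_equal(res2$rwc_mrc, 1)
  expect_equal(res2$d_crit_10 + res2$d_crit_5 + res2$d_mod, 0L)
  # no day above 75% capacity: mrc undefined and flagged
  sdays3 <- make_strain_days(c(50, 60), rwc = c(0.9, 0.9))
  expect_warning(res3 <- strain_thresholds(sdays3), "rwc_mrc undefined")
  expect_true(is.na(res3$rwc_mrc))
})

test_that("censoring logic: rwc_crit numeric iff some day fell below 10%", {
  set.seed(5)
  for (i in 1:8) {
    caps <- runif(12, 0, 120)
    sdays <- make_strain_days(caps, rwc = runif(12, 0.6, 1.05))
    res <- suppressWarnings(strain_thresholds(sdays))
    expect_identical(is.na(res$rwc_crit), res$d_crit_10 == 0L)
  }
})

test_that("VPD-capacity correlation runs over stress days only", {
  n <- 40
  dates <- as.Date("2023-07-01") + seq_len(n) - 1
  vpd_daily <- tibble::tibble(date = dates, vpd_max = seq(0.5, 2, length.out = n))
  # capacity proportional to VPD on stress days -> r = 1
  sdays <- make_strain_days(seq(10, 70, length.out = n), rwc = rep(0.9, n))
  r <- vpd_capacity_correlation(sdays, vpd_daily)
  expect_equal(r$vpd_capacity_r, 1)
  # anti-correlated
  sdays2 <- make_strain_days(seq(70, 10, length.out = n), rwc = rep(0.9, n))
  expect_lt(vpd_capacity_correlation(sdays2, vpd_daily)$vpd_capacity_r, 0)
  # independence: |r| small at large n
  set.seed(99)
  n2 <- 4000
  vd <- tibble::tibble(date = as.Date("2023-07-01") + seq_len(n2) - 1,
                       vpd_max = runif(n2, 0.2, 2.5))
  sdays3 <- make_strain_days(runif(n2, 5, 100), rwc = rep(0.9, n2))
  expect_lt(abs(vpd_capacity_correlation(sdays3, vd)$vpd_capacity_r), 0.06)
  # excluded (well-hydrated) days do not contribute
  sdays4 <- make_strain_days(c(10, 20, 30, 40, 99), rwc = c(0.9, 0.9, 0.9, 0.9, 0.99))
  r4 <- vpd_capacity_correlation(sdays4, vpd_daily)
  expect_equal(r4$n_stress_days, 4L)
  # too few pairs -> flagged undefined
  sdays5 <- make_strain_days(c(10, 20), rwc = c(0.9, 0.9))
  expect_warning(r5 <- vpd_capacity_correlation(sdays5, vpd_daily), "undefined")
  expect_true(is.na(r5$vpd_capacity_r))
})
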