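test_that("percentile uses linear interpolation between order statistics", {
  expect_equal(percentile(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(percentile(1:100, 99), 99.01)
  expect_equal(percentile(rep(7.3, 20), 42), 7.3)
  expect_error(percentile(numeric(0), 50), "no finite values")
  expect_error(percentile(c(NA, NaN), 10), "no finite values")
})

test_that("summarise_days reduces days to trimmed extremes and RWC", {
  # constant series: zero range, constant rwc
  cal <- make_calibrated(3, function(h, d) 0.5)
  days <- summarise_days(cal)
  expect_equal(nrow(days), 3)
  expect_equal(days$daily_range, rep(0, 3))
  expect_equal(unique(days$rwc_day_max), 1)

  # pure sinusoid of amplitude a: daily range close to 2a
  a <- 0.03
  cal <- make_calibrated(4, function(h, d) 0.5 + a * sin(2 * pi * h / 24))
  days <- summarise_days(cal,
                         theta_turgid = tibble::tibble(tree_id = "t1",
                                                       theta_turgid = 0.53))
  expect_equal(days$daily_range, rep(2 * a, 4), tolerance = 0.02)
  expect_lte(max(days$daily_range), 2 * a)
  # brute-force within-day percentiles on day 1
  d1 <- cal$theta[as.Date(cal$timestamp, tz = "UTC") == as.Date("2023-07-01")]
  expect_equal(days$theta_day_hi[1],
               quantile(d1, 0.99, type = 7, names = FALSE))
  expect_equal(days$rwc_day_max[1], days$theta_day_hi[1] / 0.53)
})

test_that("days below the completeness floor are excluded", {
  cal <- make_calibrated(2, function(h, d) 0.5)
  # leave day 2 with 10 of 96 samples
  day2 <- as.Date(cal$timestamp, tz = "UTC") == as.Date("2023-07-02")
  cal <- cal[!day2 | seq_along(cal$theta) %% 10 == 0, ]
  days <- summarise_days(cal, cadence_minutes = 15)
  expect_equal(days$date, as.Date("2023-07-01"))
  # a permissive floor keeps it
  days2 <- summarise_days(cal, completeness = 0.05, cadence_minutes = 15)
  expect_equal(nrow(days2), 2)
})

test_that("storage_metrics reproduces the published per-tree arithmetic", {
  skip_if_not_installed("stemwater")
  # deficit computed from theta_t / theta_d pairs of the field study
  expect_equal(100 * (0.673 - 0.436) / 0.673, 35.2, tolerance = 0.005)
  cal <- make_calibrated(3, function(h, d) 0.45 + 0.03 * sin(2 * pi * h / 24))
  m <- storage_metrics(cal)
  expect_equal(m$theta_turgid, percentile(cal$theta, 99))
  expect_equal(m$theta_dry, percentile(cal$theta, 1))
  expect_equal(m$seasonal_delta, m$theta_turgid - m$theta_dry)
  expect_equal(m$water_deficit_pct,
               100 * m$seasonal_delta / m$theta_turgid)
  expect_equal(m$cv_pct, 100 * sd(cal$theta) / mean(cal$theta))
  expect_true(m$theta_dry <= m$theta_mean & m$theta_mean <= m$theta_turgid)
})

test_that("diurnal delta never exceeds seasonal delta", {
  set.seed(42)
  for (i in 1:10) {
    n_days <- sample(3:8, 1)
    base <- runif(1, 0.3, 0.6)
    cal <- make_calibrated(n_days, function(h, d)
      base + cumsum(rnorm(length(h), sd = 0.002)))
    m <- storage_metrics(cal)
    expect_lte(m$diurnal_delta, m$seasonal_delta + 1e-12)
  }
})

test_that("sapwood area is the annulus with sane limits", {
  expect_equal(sapwood_area(0.22, 0.035), 0.02034, tolerance = 1e-4)
  r <- 0.11
  expect_equal(sapwood_area(0.22, r - 1e-9), pi * r^2, tolerance = 1e-6)
  expect_equal(sapwood_area(0.22, 1e-9), 0, tolerance = 1e-8)
  expect_error(sapwood_area(0.22, 0.11), "radius")
  expect_error(sapwood_area(0.22, 0.2), "radius")
})

test_that("active storage: palm cylinder and tapered dicot sapwood", {
  expect_equal(active_storage("palm", 13, 0.22, 0.728), 0.36,
               tolerance = 0.005)
  expect_equal(active_storage("palm", 13, 0.22, 0), 0)
  expect_equal(
    active_storage("dicot", 20, 0.22, 0.423, sapwood_depth = 0.035),
    0.086, tolerance = 0.001)
  # linear in theta and in height
  s1 <- active_storage("palm", 10, 0.3, 0.4)
  expect_equal(active_storage("palm", 10, 0.3, 0.8), 2 * s1)
  expect_equal(active_storage("palm", 20, 0.3, 0.4), 2 * s1)
  expect_error(active_storage("palm", -1, 0.22, 0.7), "height")
  expect_error(active_storage("liana", 10, 0.2, 0.5), "group")
})

test_that("relative soil water is a plain normalisation", {
  expect_equal(relative_soil_water(0.2923, 0.2923), 1)
  expect_equal(relative_soil_water(0.19, 0.2923), 0.65, tolerance = 0.001)
  expect_equal(relative_soil_water(0, 0.3), 0)
  expect_error(relative_soil_water(0.2, 0), "positive")
})
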