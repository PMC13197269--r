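test_that("invalid configurations fail naming the offending field", {
  expect_error(scenario_config(n_days = 1), "n_days")
  expect_error(scenario_config(cadence_minutes = 17), "cadence")
  expect_error(scenario_config(noise = list(epsilon_sd = -1, soil_sd = 0)),
               "noise")
  expect_error(scenario_config(refill_cutoff = 1.2), "refill_cutoff")
  bad_trees <- scenario_trees()
  bad_trees$theta_dry_true[1] <- 0.9               # above turgid
  expect_error(scenario_config(trees = bad_trees), "theta_dry_true")
})

test_that("degenerate no-dynamics scenario is the flat baseline exactly", {
  tr <- scenario_trees()[1:2, ]
  tr$diurnal_amp_true <- 0
  cfg <- scenario_config(
    n_days = 4, trees = tr,
    season = list(wet_end = 4, rewet_start = 5),
    soil = list(vwc_initial = 0.30, vwc_max = 0.32, vwc_floor = 0.30,
                decay_rate = 0, recharge_per_mm = 0, depths_cm = 100),
    climate = list(t_stem_mean = 28, t_stem_amp = 4, t_air_mean = 26,
                   t_air_amp = 4, rh_max = 98, rh_min = 65,
                   rain_rate = 0, rain_depth_mm = 10),
    noise = list(epsilon_sd = 0, soil_sd = 0), seed = 2)
  sc <- generate_scenario(cfg)
  cal <- calibrate_series(sc$sensor)
  expect_equal(cal$theta, rep(tr$theta_turgid_true, each = 4 * 96),
               tolerance = 1e-12)
  days <- summarise_days(cal)
  expect_equal(days$daily_range, rep(0, 8), tolerance = 1e-12)
})

test_that("generation is deterministic given seed and sized as configured", {
  cfg <- short_config(n_days = 6, seed = 123)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$sensor, b$sensor)
  expect_identical(a$soil, b$soil)
  expect_identical(a$meteo, b$meteo)
  c <- generate_scenario(short_config(n_days = 6, seed = 124))
  expect_false(identical(a$sensor$epsilon, c$sensor$epsilon))
  # one row per tree per cadence step
  expect_equal(nrow(a$sensor), 7 * 6 * 96)
  expect_equal(nrow(a$meteo), 6 * 96)
  expect_equal(nrow(a$soil), 3 * 6 * 24)          # hourly, three depths
})

test_that("generated permittivities stay above the calibration root", {
  sc <- generate_scenario(short_config(n_days = 10, seed = 99))
  expect_true(all(sc$sensor$epsilon > (0.396 / 0.2227)^2))
  expect_true(all(sc$soil$vwc > 0 & sc$soil$vwc < 1))
  expect_true(all(sc$meteo$rh >= 0 & sc$meteo$rh <= 100))
  expect_true(all(sc$meteo$precipitation >= 0))
})

test_that("zero-noise generation inverts back to the true water content", {
  cfg <- short_config(n_days = 6, seed = 4,
                      noise = list(epsilon_sd = 0, soil_sd = 0))
  sc <- generate_scenario(cfg)
  cal <- calibrate_series(sc$sensor)
  expect_equal(cal$theta, sc$theta_true$theta, tolerance = 1e-12)
})

test_that("pipeline recovers turgid content and diurnal amplitude", {
  sc <- generate_scenario(scenario_config(seed = 11))
  cal <- calibrate_series(sc$sensor)
  m <- storage_metrics(cal, trees = sc$trees)
  j <- dplyr::inner_join(m, sc$truth, by = "tree_id")
  expect_true(all(abs(j$theta_turgid - j$theta_turgid_true) < 0.01))
  expect_true(all(abs(j$diurnal_delta - j$diurnal_amp_true) /
                    j$diurnal_amp_true < 0.15))
})

test_that("scenario round-trips through CSV to six decimals", {
  dir <- withr::local_tempdir()
  sc <- generate_scenario(short_config(n_days = 3, seed = 21))
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(paths)))
  sensor <- read_sensor_csv(paths[["sensor"]])
  expect_equal(sensor$epsilon, sc$sensor$epsilon, tolerance = 1e-6)
  expect_identical(sensor$timestamp, sc$sensor$timestamp)
  soil <- read_soil_csv(paths[["soil"]])
  expect_equal(soil$vwc, sc$soil$vwc, tolerance = 1e-6)
  meteo <- read_meteo_csv(paths[["meteo"]])
  expect_equal(meteo$rh, sc$meteo$rh, tolerance = 1e-6)
  trees <- read_trees_csv(paths[["trees"]])
  expect_identical(trees$tree_id, sc$trees$tree_id)

  # empty tree list: header-only sensor file
  sc0 <- sc
  sc0$sensor <- sc$sensor[0, ]
  p0 <- write_scenario(sc0, dir)
  expect_equal(nrow(read_sensor_csv(p0[["sensor"]])), 0)
})
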