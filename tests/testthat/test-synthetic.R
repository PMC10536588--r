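test_that("dough yield follows the flour/water mass ratio", {
  expect_equal(dough_yield(500, 500), 200)
  expect_equal(dough_yield(100, 0), 100)
  expect_equal(dough_yield(100, 55), 155)
  expect_error(dough_yield(0, 100), "positive")
  expect_error(dough_yield(-5, 100), "positive")
  expect_error(dough_yield(100, -1), "non-negative")
})

test_that("kinetics reproduce the logistic pH drop and linear TTA rise", {
  cfg <- sim_config(duration = 20, temperature = 30, pH_midpoint = 10)
  k0 <- kinetics(cfg, 0)
  expect_equal(k0$ph, cfg$pH0, tolerance = 1e-3)
  km <- kinetics(cfg, cfg$pH_midpoint)
  expect_equal(km$ph, (cfg$pH0 + cfg$pH_inf) / 2)
  expect_equal(km$activity, 0.5)

  cfg2 <- sim_config(duration = 10, temperature = 30, TTA0 = 4,
                     TTA_slope_ref = 0.7, q10 = 2)
  expect_equal(kinetics(cfg2, 10)$tta, 11)
  expect_error(kinetics(cfg2, 10.5), "outside")
  expect_error(kinetics(cfg2, -1), "outside")
})

test_that("pH is non-increasing and TTA non-decreasing for varied configs", {
  set.seed(401)
  for (i in 1:20) {
    cfg <- sim_config(duration = runif(1, 2, 15),
                      temperature = runif(1, 24, 36),
                      pH0 = runif(1, 5.2, 6.2), pH_inf = runif(1, 3.2, 4),
                      pH_rate_ref = runif(1, 0.2, 2),
                      pH_midpoint = runif(1, 1, 8),
                      TTA_slope_ref = runif(1, 0, 1.5),
                      q10 = runif(1, 1, 3))
    k <- kinetics(cfg, seq(0, cfg$duration, length.out = 200))
    expect_true(all(diff(k$ph) <= 1e-12))
    expect_true(all(diff(k$tta) >= -1e-12))
    expect_true(all(k$activity >= 0 & k$activity <= 1))
  }
})

test_that("warmer fermentations reach the half-way pH drop strictly earlier", {
  half_time <- function(temp) {
    cfg <- sim_config(duration = 20, temperature = temp, q10 = 2)
    tt <- seq(0, 20, by = 0.001)
    ph <- kinetics(cfg, tt)$ph
    half <- (cfg$pH0 + cfg$pH_inf) / 2
    tt[which(ph <= half)[1]]
  }
  expect_lt(half_time(32), half_time(28))
})

test_that("a 10 h run at 300 s cadence yields 120 measurement cycles", {
  run <- simulate_run(sim_config(duration = 10, seed = 3))
  expect_equal(length(unique(floor(run$trace$time_s / 300))), 120)
  expect_equal(nrow(run$offline), 11)
  expect_true(all(run$offline$time_h >= 0 & run$offline$time_h <= 10))
})

test_that("cycle count drops by exactly the cycles inside declared gaps", {
  cfg <- sim_config(duration = 1, seed = 5,
                    gap_spec = list(c(0.25, 0.5)))
  run <- simulate_run(cfg)
  cycles <- unique(floor(run$trace$time_s / 300))
  # cycles start at k/12 h; k = 3, 4, 5 start inside [0.25, 0.5)
  expect_equal(length(cycles), 9)
  expect_false(any(cycles %in% 3:5))
})

test_that("identical configurations reproduce a run bit for bit", {
  cfg <- sim_config(duration = 2, seed = 99)
  r1 <- simulate_run(cfg, "X")
  r2 <- simulate_run(cfg, "X")
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  r3 <- simulate_run(sim_config(duration = 2, seed = 100), "X")
  expect_false(identical(r1$trace$tgs822, r3$trace$tgs822))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(simulate_run(sim_config(duration = 1, seed = 77)))
  expect_identical(runif(3), a)
})

test_that("with zero gains the signal is exactly baseline plus drift", {
  cfg <- sim_config(duration = 1, noise_sd = 0, sensor_gains = c(0, 0, 0),
                    drift_rate = 0.12, seed = 1)
  run <- simulate_run(cfg)
  for (i in 1:3) {
    expected <- cfg$sensor_baselines[i] + 0.12 * run$trace$time_s / 3600
    expect_equal(run$trace[[c("tgs822", "tgs813", "mq3")[i]]], expected)
  }
})

test_that("noiseless peak height above baseline matches the kernel closed form", {
  # exponent 1 so the amplitude law is gain * activity; rise time = injection
  # time makes the kernel maximum exactly 1
  cfg <- quiet_config(duration = 2, sensor_exponents = c(1, 1, 1), seed = 2)
  run <- simulate_run(cfg)
  ft <- build_feature_table(run$trace)
  act <- kinetics(cfg, ft$t_mid_s %/% 300 * 300 / 3600)$activity
  for (i in 1:3) {
    ph <- ft[[paste0("ph_", c("tgs822", "tgs813", "mq3")[i])]]
    bl <- ft[[paste0("bl_", c("tgs822", "tgs813", "mq3")[i])]]
    expect_equal(ph - bl, cfg$sensor_gains[i] * act, tolerance = 1e-10)
  }
})

test_that("config files round-trip through the key/value format", {
  cfg <- sim_config(duration = 3, temperature = 28, seed = 17,
                    gap_spec = list(c(0.5, 0.75)))
  path <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  r1 <- simulate_run(cfg)
  r2 <- simulate_run(cfg2)
  expect_identical(r1$trace$mq3, r2$trace$mq3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration = 0), "duration")
  expect_error(sim_config(pH0 = 3.5, pH_inf = 3.6), "pH0")
  expect_error(sim_config(TTA_slope_ref = -1), "TTA_slope_ref")
  expect_error(sim_config(sensor_gains = c(1, 1)), "sensor_gains")
  expect_error(sim_config(cadence = 30, injection_delay = 25,
                          injection_duration = 10), "cadence")
  expect_error(sim_config(sample_rate = 0.01), "20 samples")
  expect_error(sim_config(gap_spec = list(c(2, 1))), "gap_spec")
})
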