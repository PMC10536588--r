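test_that("offline samples match the nearest interval midpoint", {
  run <- simulate_run(sim_config(duration = 2, seed = 51), "m1")
  ft <- build_feature_table(run$trace)
  # offline exactly at midpoints: zero time offset
  off <- offline_series(ft$t_mid_s[c(1, 5, 9)] / 3600, c(5.5, 5.0, 4.5),
                        c(6, 7, 8), "m1")
  m <- match_offline(ft, off)
  expect_equal(m$t_mid_s, ft$t_mid_s[c(1, 5, 9)])

  # brute-force nearest neighbour agreement on the hourly grid
  m2 <- match_offline(ft, run$offline)
  brute <- vapply(run$offline$time_h * 3600, function(t) {
    ft$t_mid_s[which.min(abs(ft$t_mid_s - t))]
  }, 0)
  expect_equal(m2$t_mid_s, brute)
})

test_that("offline samples inside a data gap are dropped with a warning", {
  cfg <- sim_config(duration = 3, seed = 52, gap_spec = list(c(0.9, 2.1)))
  run <- simulate_run(cfg, "g")
  ft <- build_feature_table(run$trace)
  expect_warning(m <- match_offline(ft, run$offline), "no matching interval")
  expect_equal(nrow(m), nrow(run$offline) - 2)  # 1 h and 2 h samples dropped
})

test_that("sensor-signal OLS recovers an exact linear law to machine precision", {
  lin <- linear_law_run()
  fit <- fit_sensor_signal(lin$run, target = "ph")
  expect_equal(unname(fit$coefficients), lin$K, tolerance = 1e-10)
  pred <- predict(fit, lin$run)
  expect_equal(pred$value, lin$C, tolerance = 1e-10)
  met <- evaluate_calibration(fit, lin$run)
  expect_lt(met$pct_error, 1e-6)
})

test_that("noisy coefficient estimates stay within three standard errors", {
  lin <- linear_law_run(seed = 53)
  ft <- lin$features
  X <- height_regressors(ft)
  sigma <- 0.05
  set.seed(54)
  y <- lin$C + rnorm(nrow(ft), 0, sigma)
  off <- offline_series(ft$t_mid_s / 3600, y, seq_along(y))
  fit <- fit_sensor_signal(ft, off, target = "ph")
  se <- sigma * sqrt(diag(solve(crossprod(cbind(1, X)))))
  expect_true(all(abs(fit$coefficients - lin$K) < 3 * se))
})

test_that("no coefficient vector beats the OLS fit on its own training SSE", {
  run <- simulate_run(sim_config(duration = 10, seed = 55), "o")
  fit <- fit_sensor_signal(run, target = "ph")
  ft <- build_feature_table(run$trace)
  m <- match_offline(ft, run$offline)
  X <- cbind(1, height_regressors(m))
  sse <- function(K) sum((m$ph - X %*% K)^2)
  expect_equal(sse(fit$coefficients), fit$sse_fit, tolerance = 1e-10)
  set.seed(56)
  for (i in 1:100) {
    expect_gte(sse(fit$coefficients + rnorm(4, 0, 0.1)), fit$sse_fit)
  }
})

test_that("rank-deficient designs are rejected naming the collinear channel", {
  run <- simulate_run(quiet_config(duration = 6,
                                   sensor_exponents = c(1, 1, 1), seed = 57))
  # equal exponents make all channels proportional: rank-1 design
  expect_error(fit_sensor_signal(run, target = "ph"), "collinear")
})

test_that("PCA regression is exact when targets are linear in a 2-D feature plane", {
  run <- simulate_run(quiet_config(seed = 58), "p")
  ft <- build_feature_table(run$trace)
  orc <- oracle_autoscale_pcs(as.matrix(as.data.frame(ft)[, feat6]))
  C <- 4.2 + 0.6 * orc$scores[, 1] - 0.2 * orc$scores[, 2]
  off <- offline_series(ft$t_mid_s / 3600, C, seq_along(C), "p")
  fit <- fit_pca_regression(ft, off, target = "ph")
  expect_equal(unname(fit$coefficients), c(4.2, 0.6, -0.2), tolerance = 1e-8)
  met <- evaluate_calibration(fit, ferm_run(run$trace, off, run_id = "p"))
  expect_lt(met$pct_error, 1e-6)
  expect_equal(r_squared(predict(fit, ft), C), 1, tolerance = 1e-9)
})

test_that("package PCA axes match the eigendecomposition oracle", {
  set.seed(59)
  run <- simulate_run(sim_config(duration = 10, seed = 59), "q")
  ft <- build_feature_table(run$trace)
  fit <- fit_pca_regression(ft, run$offline, target = "ph")
  orc <- oracle_autoscale_pcs(as.matrix(as.data.frame(ft)[, feat6]))
  expect_equal(abs(colSums(fit$loadings * orc$vectors)), c(1, 1),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$center, orc$center, ignore_attr = TRUE)
  expect_equal(fit$scale, orc$scale, ignore_attr = TRUE)
})

test_that("duplicating every row leaves PCA loadings and coefficients unchanged", {
  run <- simulate_run(sim_config(duration = 5, seed = 60), "d")
  ft <- build_feature_table(run$trace)
  fit1 <- fit_pca_regression(ft, run$offline, target = "tta")
  run2 <- pool_runs(list(run, run))
  fit2 <- fit_pca_regression(run2, target = "tta")
  expect_equal(fit2$loadings, fit1$loadings, tolerance = 1e-12)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-10)
})

test_that("zero-variance features are dropped with zero-padded loadings", {
  run <- simulate_run(sim_config(duration = 5, seed = 61), "z")
  ft <- build_feature_table(run$trace)
  ft$ph_mq3 <- 7  # dead sensor: constant reading
  expect_warning(fit <- fit_pca_regression(ft, run$offline, target = "ph"),
                 "zero-variance")
  expect_equal(unname(fit$loadings["ph_mq3", ]), c(0, 0))
  expect_equal(nrow(predict(fit, ft)), nrow(ft))
})

test_that("interval scores are affine in the amplitude of scaled cycle copies", {
  amp <- c(1, 2, 3.5, 5, 7, 10)
  tr <- rank1_trace(amp)
  off <- offline_series(c(0, 0.5), c(5, 4), c(5, 8), "rank1")
  fit <- fit_interval_pca(tr, off, target = "ph", L = 40)
  expect_equal(fit$explained_variance_1, 1, tolerance = 1e-12)
  scores <- local({
    segs <- segment_intervals(tr, 300)
    V <- t(vapply(segs, function(s) {
      grid <- seq(s$time_s[1], s$time_s[length(s$time_s)], length.out = 40)
      c(approx(s$time_s, s$channels[, 1], grid)$y,
        approx(s$time_s, s$channels[, 2], grid)$y,
        approx(s$time_s, s$channels[, 3], grid)$y)
    }, numeric(120)))
    as.vector(sweep(V, 2, fit$center) %*% fit$loading)
  })
  co <- coef(lm(scores ~ amp))
  expect_equal(unname(cor(scores, amp)^2), 1, tolerance = 1e-12)
  expect_gt(abs(co[2]), 0)
})

test_that("identical intervals give a degenerate-score-variance error", {
  tr <- rank1_trace(rep(2, 5))
  off <- offline_series(c(0, 0.4), c(5, 4.5), c(5, 6))
  expect_error(fit_interval_pca(tr, off, target = "ph", L = 30),
               "degenerate score variance")
})

test_that("interval method tracks a monotone fermentation closely", {
  run <- simulate_run(sim_config(duration = 10, seed = 62), "mono")
  fit <- fit_interval_pca(run, target = "ph")
  expect_gt(fit$explained_variance_1, 0.95)
  met <- evaluate_calibration(fit, run)
  expect_lt(met$pct_error, 10)
  # score and interpolated pH must be monotonically associated
  pred <- predict(fit, run)
  ref <- reference_series(run$offline, pred$t_mid_s, "ph")
  expect_lt(cor(pred$value, ref), 1)
  expect_gt(cor(pred$value, ref), 0.95)
})

test_that("pooling one run or identical copies reproduces the single-run fit", {
  run <- simulate_run(sim_config(duration = 5, seed = 63), "s")
  single <- fit_sensor_signal(run, target = "ph")
  pooled1 <- fit_sensor_signal(pool_runs(list(run)), target = "ph")
  expect_equal(pooled1$coefficients, single$coefficients)
  pooled2 <- fit_sensor_signal(pool_runs(list(run, run)), target = "ph")
  expect_equal(pooled2$coefficients, single$coefficients, tolerance = 1e-10)

  int1 <- fit_interval_pca(run, target = "tta")
  int2 <- fit_interval_pca(pool_runs(list(run, run)), target = "tta")
  expect_equal(int2$coefficients, int1$coefficients, tolerance = 1e-8)
})

test_that("pooling noiseless runs from one law recovers that law", {
  lin1 <- linear_law_run(seed = 64)
  lin2 <- linear_law_run(seed = 65)
  pool <- pool_runs(list(lin1$run, lin2$run))
  fit <- fit_sensor_signal(pool, target = "ph")
  expect_equal(unname(fit$coefficients), lin1$K, tolerance = 1e-8)
})

test_that("cadence mismatch across pooled runs is rejected", {
  r1 <- simulate_run(sim_config(duration = 2, seed = 66, cadence = 300), "a")
  r2 <- simulate_run(sim_config(duration = 2, seed = 67, cadence = 600), "b")
  expect_error(pool_runs(list(r1, r2)), "cadence mismatch")
})

test_that("predictions are invariant to a constant baseline convention shift", {
  run <- simulate_run(sim_config(duration = 10, seed = 68), "b")
  ft <- build_feature_table(run$trace)
  fit1 <- fit_sensor_signal(ft, run$offline, target = "ph")
  ft2 <- ft
  shift <- c(0.7, -0.3, 1.1)
  ft2$bl_tgs822 <- ft$bl_tgs822 + shift[1]
  ft2$bl_tgs813 <- ft$bl_tgs813 + shift[2]
  ft2$bl_mq3 <- ft$bl_mq3 + shift[3]
  fit2 <- fit_sensor_signal(ft2, run$offline, target = "ph")
  expect_equal(predict(fit2, ft2)$value, predict(fit1, ft)$value,
               tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients[-1]), unname(fit1$coefficients[-1]),
               tolerance = 1e-8)
  expect_false(isTRUE(all.equal(fit2$coefficients[1], fit1$coefficients[1])))
})

test_that("models with zero slopes predict a constant intercept", {
  run <- simulate_run(sim_config(duration = 4, seed = 69), "c")
  fit <- fit_sensor_signal(run, target = "ph")
  fit$coefficients[2:4] <- 0
  fit$coefficients[1] <- 4.0
  expect_equal(unique(predict(fit, run)$value), 4.0)
})

test_that("repeated fits on identical data yield identical models", {
  run <- simulate_run(sim_config(duration = 5, seed = 70), "r")
  f1 <- fit_pca_regression(run, target = "ph")
  f2 <- fit_pca_regression(run, target = "ph")
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$coefficients, f2$coefficients)
  g1 <- fit_interval_pca(run, target = "ph", L = 30)
  g2 <- fit_interval_pca(run, target = "ph", L = 30)
  expect_identical(g1$loading, g2$loading)
})
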