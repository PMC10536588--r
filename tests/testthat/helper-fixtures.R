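# Shared fixtures, all generated in code.

# The six independent variables, in feature-table column order.
feat6 <- c("ph_tgs822", "pa_tgs822", "ph_tgs813", "pa_tgs813",
           "ph_mq3", "pa_mq3")

# Noiseless, drift-free configuration for exact-arithmetic checks.
quiet_config <- function(duration = 10, ...) {
  sim_config(duration = duration, noise_sd = 0, drift_rate = 0,
             offline_ph_sd = 0, offline_tta_sd = 0, ...)
}

# Feature-table regressors of the sensor-signal method (peak height).
height_regressors <- function(ft) {
  cbind(ft$ph_tgs822 - ft$bl_tgs822,
        ft$ph_tgs813 - ft$bl_tgs813,
        ft$ph_mq3 - ft$bl_mq3)
}

# A run whose pH is an exact linear function of the sensor-signal regressors,
# with the offline table sampled at every interval midpoint so matching and
# reference interpolation are exact.
linear_law_run <- function(K = c(4.5, 0.8, -0.5, 0.3), seed = 11) {
  run <- simulate_run(quiet_config(seed = seed), "lin")
  ft <- build_feature_table(run$trace)
  C <- K[1] + as.vector(height_regressors(ft) %*% K[-1])
  off <- offline_series(ft$t_mid_s / 3600, C, seq_along(C), "lin")
  list(run = ferm_run(run$trace, off, run_id = "lin"),
       features = ft, K = K, C = C)
}

# Independent PCA oracle: eigendecomposition of the covariance of the
# population-autoscaled matrix, with the package's sign convention applied.
oracle_autoscale_pcs <- function(M, k = 2) {
  center <- colMeans(M)
  sds <- sqrt(colMeans(sweep(M, 2, center)^2))
  Z <- sweep(sweep(M, 2, center), 2, sds, "/")
  ev <- eigen(stats::cov(Z), symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  list(center = center, scale = sds, vectors = V, scores = Z %*% V)
}

# A hand-built trace of n_int cycles in which every cycle is amp[k] times one
# common template shape (per channel), at 1 Hz and 300 s cadence.
rank1_trace <- function(amp, base = c(0, 0, 0)) {
  n_int <- length(amp)
  tau <- 0:299
  shape <- pmax(1 - abs(tau - 100) / 50, 0)  # triangular template
  time_s <- numeric(0); ch <- matrix(0, 0, 3)
  for (k in seq_len(n_int)) {
    time_s <- c(time_s, (k - 1) * 300 + tau)
    ch <- rbind(ch, cbind(base[1] + amp[k] * shape,
                          base[2] + amp[k] * 0.5 * shape,
                          base[3] + amp[k] * 2 * shape))
  }
  sensor_trace(time_s, ch[, 1], ch[, 2], ch[, 3], "rank1")
}
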