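#' Dough yield
#'
#' Dough yield (DY) characterises dough consistency as the mass ratio
#' \eqn{DY = (m_{flour} + m_{water}) \times 100 / m_{flour}}. A DY of 150--160
#' gives a firm dough; a DY of 200 is already liquid enough for stirred
#' fermenter runs.
#'
#' @param flour_mass Flour mass in grams; must be positive.
#' @param water_mass Water mass in grams; must be non-negative.
#' @return Dimensionless dough yield.
#' @examples
#' dough_yield(500, 500) # 200
#' @export
dough_yield <- function(flour_mass, water_mass) {
  if (!is.numeric(flour_mass) || !is.numeric(water_mass)) {
    stop("flour_mass and water_mass must be numeric")
  }
  if (any(flour_mass <= 0)) stop("flour_mass must be positive")
  if (any(water_mass < 0)) stop("water_mass must be non-negative")
  (flour_mass + water_mass) * 100 / flour_mass
}

#' Simulation configuration for one fermentation run
#'
#' Bundles the kinetic, sensor and sampling parameters of a simulated
#' sourdough fermentation monitored by a pulsed three-channel MOS gas sensor
#' array (channels TGS822, TGS813, MQ3). Defaults describe a 10 h fermentation
#' at DY 200 sampled every 5 minutes, with hourly offline pH/TTA references.
#'
#' @param duration Run length in hours.
#' @param temperature Fermentation temperature in deg C.
#' @param flour_label Flour type token (e.g. "A", "B", "C").
#' @param flour_mass,water_mass Dough composition in grams (defaults give DY 200).
#' @param pH0,pH_inf Initial and asymptotic pH of the logistic acidification curve.
#' @param pH_rate_ref Logistic rate (1/h) at the 30 deg C reference temperature.
#' @param pH_midpoint Time (h) of the half-way pH drop at 30 deg C.
#' @param TTA0 Initial total titratable acidity (mL 0.1 M NaOH per 10 g).
#' @param TTA_slope_ref TTA increase rate (mL/(10 g h)) at 30 deg C.
#' @param q10 Temperature acceleration factor per 10 deg C (>= 0; > 1 means
#'   faster fermentation when warmer).
#' @param sensor_gains Length-3 positive gains (signal units per activity unit).
#' @param sensor_exponents Length-3 positive response exponents: channel
#'   \eqn{i} responds to \eqn{activity^{p_i}}. MOS sensors follow power-law
#'   response curves with sensor-specific exponents; unequal exponents also
#'   make the three channels carry independent information.
#' @param sensor_baselines Length-3 clean-gas signal levels.
#' @param drift_rate Common linear baseline drift (signal units per hour).
#' @param noise_sd Gaussian noise sd per raw sample (signal units).
#' @param pulse_rise Rise time (s) of the measurement pulse.
#' @param pulse_decay Exponential decay constant (s) during oxygen flushing.
#' @param sample_rate Sensor sampling rate (Hz).
#' @param cadence Measurement cycle length (s); one pulse per cycle.
#' @param injection_delay Idle time (s) between cycle start and pump start;
#'   provides pre-injection samples for baseline estimation.
#' @param injection_duration Pump time (s) per cycle.
#' @param offline_interval Spacing (h) of offline pH/TTA samples.
#' @param offline_ph_sd,offline_tta_sd Gaussian sd of offline measurement noise
#'   (the default pH sd of 0.033 treats the instrument's +/- 0.1 pH accuracy
#'   as a 3-sigma band).
#' @param gap_spec Optional list of \code{c(start_h, end_h)} windows during
#'   which the acquisition system is down; cycles starting inside a window are
#'   omitted entirely.
#' @param seed Integer seed; identical configurations reproduce runs exactly.
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso [simulate_run()], [kinetics()]
#' @export
sim_config <- function(duration = 10, temperature = 30, flour_label = "A",
                       flour_mass = 500, water_mass = 500,
                       pH0 = 5.8, pH_inf = 3.6, pH_rate_ref = 0.9,
                       pH_midpoint = 5, TTA0 = 6, TTA_slope_ref = 0.7,
                       q10 = 2,
                       sensor_gains = c(1.0, 0.8, 1.2),
                       sensor_exponents = c(1.0, 0.7, 1.3),
                       sensor_baselines = c(0.5, 0.6, 0.4),
                       drift_rate = 0.005, noise_sd = 0.01,
                       pulse_rise = 10, pulse_decay = 60,
                       sample_rate = 1, cadence = 300,
                       injection_delay = 30, injection_duration = 10,
                       offline_interval = 1,
                       offline_ph_sd = 0.033, offline_tta_sd = 0.1,
                       gap_spec = NULL, seed = 1L) {
  cfg <- list(duration = duration, temperature = temperature,
              flour_label = as.character(flour_label),
              flour_mass = flour_mass, water_mass = water_mass,
              pH0 = pH0, pH_inf = pH_inf, pH_rate_ref = pH_rate_ref,
              pH_midpoint = pH_midpoint, TTA0 = TTA0,
              TTA_slope_ref = TTA_slope_ref, q10 = q10,
              sensor_gains = as.numeric(sensor_gains),
              sensor_exponents = as.numeric(sensor_exponents),
              sensor_baselines = as.numeric(sensor_baselines),
              drift_rate = drift_rate, noise_sd = noise_sd,
              pulse_rise = pulse_rise, pulse_decay = pulse_decay,
              sample_rate = sample_rate, cadence = cadence,
              injection_delay = injection_delay,
              injection_duration = injection_duration,
              offline_interval = offline_interval,
              offline_ph_sd = offline_ph_sd, offline_tta_sd = offline_tta_sd,
              gap_spec = gap_spec, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$duration), length(cfg$duration) == 1)
  if (cfg$duration <= 0) stop("duration must be positive")
  if (cfg$pH0 <= cfg$pH_inf) stop("pH0 must exceed pH_inf")
  if (cfg$TTA_slope_ref < 0) stop("TTA_slope_ref must be >= 0")
  if (cfg$pH_rate_ref < 0) stop("pH_rate_ref must be >= 0")
  if (cfg$q10 <= 0) stop("q10 must be positive")
  if (length(cfg$sensor_gains) != 3 || any(cfg$sensor_gains < 0)) {
    stop("sensor_gains must be 3 non-negative values")
  }
  if (length(cfg$sensor_baselines) != 3) {
    stop("sensor_baselines must have 3 values")
  }
  if (length(cfg$sensor_exponents) != 3 || any(cfg$sensor_exponents <= 0)) {
    stop("sensor_exponents must be 3 positive values")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$flour_mass <= 0) stop("flour_mass must be positive")
  if (cfg$cadence <= cfg$injection_delay + cfg$injection_duration) {
    stop("cadence must exceed injection_delay + injection_duration")
  }
  if (cfg$sample_rate * cfg$cadence < 20) {
    stop("sample_rate * cadence must allow >= 20 samples per cycle")
  }
  if (cfg$pulse_rise <= 0 || cfg$pulse_decay <= 0) {
    stop("pulse_rise and pulse_decay must be positive")
  }
  if (!is.null(cfg$gap_spec)) {
    ok <- vapply(cfg$gap_spec, function(g) {
      is.numeric(g) && length(g) == 2 && g[1] < g[2]
    }, logical(1))
    if (!all(ok)) stop("gap_spec entries must be c(start_h, end_h) with start < end")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> flour %s, %.0f degC, %.1f h, DY %.0f, seed %d\n",
              x$flour_label, x$temperature, x$duration,
              dough_yield(x$flour_mass, x$water_mass), x$seed))
  invisible(x)
}

# Q10 time-scaling factor relative to the 30 degC reference.
q10_factor <- function(cfg) cfg$q10^((cfg$temperature - 30) / 10)

#' Fermentation kinetics at a time point
#'
#' Ground-truth state of the simulated fermentation: a logistic (sigmoid)
#' downward pH trajectory, a linear TTA increase, and a latent fermentation
#' activity driving the gas emission. Temperature accelerates the process via a
#' Q10 time-warp \eqn{u = f t}, \eqn{f = q10^{(T-30)/10}}, so at warmer
#' temperatures the half-way pH drop occurs strictly earlier.
#'
#' \deqn{pH(t) = pH_\infty + (pH_0 - pH_\infty) / (1 + e^{r (f t - t_{1/2})})}
#' \deqn{TTA(t) = TTA_0 + s\, f\, t}
#'
#' with \eqn{r} = \code{pH_rate_ref} and \eqn{s} = \code{TTA_slope_ref} the
#' 30 deg C reference constants. Activity is the normalized acidification
#' extent \eqn{a(t) = (pH_0 - pH(t))/(pH_0 - pH_\infty) \in (0, 1)}, a
#' monotone sigmoid approaching 1: the accumulated volatile load of the
#' headspace tracks fermentation progress.
#'
#' @param config A [sim_config()].
#' @param t Time(s) in hours, within \code{[0, duration]}.
#' @return A data.frame with columns \code{time_h}, \code{ph}, \code{tta},
#'   \code{activity}.
#' @export
kinetics <- function(config, t) {
  stopifnot(inherits(config, "sim_config"))
  if (any(t < 0 | t > config$duration)) {
    stop("t outside the run: must lie in [0, duration]")
  }
  f <- q10_factor(config)
  u <- f * t
  act <- 1 / (1 + exp(-config$pH_rate_ref * (u - config$pH_midpoint)))
  ph <- config$pH0 - (config$pH0 - config$pH_inf) * act
  tta <- config$TTA0 + config$TTA_slope_ref * u
  data.frame(time_h = t, ph = ph, tta = tta, activity = act)
}

# Unit-peak pulse kernel, tau = seconds since cycle start. Zero until the pump
# starts, linear rise over pulse_rise (clamped at 1), exponential decay once
# the injection ends. Closed-form maximum: min(injection_duration/pulse_rise, 1).
pulse_kernel <- function(tau, cfg) {
  on <- cfg$injection_delay
  off <- cfg$injection_delay + cfg$injection_duration
  g_end <- min(cfg$injection_duration / cfg$pulse_rise, 1)
  g <- numeric(length(tau))
  rising <- tau >= on & tau < off
  g[rising] <- pmin((tau[rising] - on) / cfg$pulse_rise, 1)
  decaying <- tau >= off
  g[decaying] <- g_end * exp(-(tau[decaying] - off) / cfg$pulse_decay)
  g
}

pulse_kernel_max <- function(cfg) min(cfg$injection_duration / cfg$pulse_rise, 1)

# Run a computation under a given seed without disturbing the caller's RNG.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

cycle_in_gap <- function(t_start_h, gap_spec) {
  if (is.null(gap_spec)) return(rep(FALSE, length(t_start_h)))
  hit <- rep(FALSE, length(t_start_h))
  for (g in gap_spec) hit <- hit | (t_start_h >= g[1] & t_start_h < g[2])
  hit
}

#' Simulate one fermentation run
#'
#' Generates a complete synthetic fermentation: the ground-truth kinetics, the
#' hourly offline reference samples (with measurement noise), and the pulsed
#' three-channel sensor trace. Each 5-minute cycle holds one peak: the pump
#' injects headspace gas for \code{injection_duration} seconds, the chamber is
#' then flushed, and the resulting pulse amplitude on channel \eqn{i} is
#' \code{gain[i] * activity(t_cycle)^exponent[i]} with the activity frozen at
#' the cycle start. The raw sample at absolute time \eqn{t} (s) is
#' \deqn{y_i(t) = baseline_i + drift\, t/3600 + gain_i\, a(t_k)^{p_i} g(\tau) + \epsilon}
#' with \eqn{g} the unit-peak pulse kernel and \eqn{\epsilon} i.i.d. Gaussian.
#' Cycles starting inside a \code{gap_spec} window are omitted entirely
#' (system crash); an identical configuration (including seed) reproduces the
#' run bit for bit.
#'
#' @param config A [sim_config()].
#' @param run_id Identifier attached to the trace and offline series.
#' @return An object of class \code{ferm_run}: a list with elements
#'   \code{trace} (sensor trace data.frame), \code{offline} (offline series),
#'   \code{truth} (ground-truth grid), \code{config}, \code{run_id}.
#' @examples
#' run <- simulate_run(sim_config(duration = 2, seed = 42))
#' nrow(run$offline)
#' @export
simulate_run <- function(config, run_id = "run1") {
  stopifnot(inherits(config, "sim_config"))
  cad <- config$cadence
  n_cycles <- floor(config$duration * 3600 / cad)
  if (n_cycles < 1) stop("duration shorter than one measurement cycle")
  t_start_s <- (seq_len(n_cycles) - 1) * cad
  keep <- !cycle_in_gap(t_start_s / 3600, config$gap_spec)

  kin <- kinetics(config, t_start_s / 3600)
  n_per <- floor(config$sample_rate * cad)
  tau <- (seq_len(n_per) - 1) / config$sample_rate
  g <- pulse_kernel(tau, config)

  with_local_seed(config$seed, {
    kept <- which(keep)
    times <- as.vector(vapply(kept, function(k) t_start_s[k] + tau,
                              numeric(n_per)))
    n_tot <- length(times)
    sig <- matrix(NA_real_, n_tot, 3)
    for (i in 1:3) {
      amp <- rep(config$sensor_gains[i] *
                   kin$activity[kept]^config$sensor_exponents[i],
                 each = n_per)
      base <- config$sensor_baselines[i] + config$drift_rate * times / 3600
      sig[, i] <- base + amp * rep(g, length(kept))
    }
    if (config$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(3 * n_tot, 0, config$noise_sd), n_tot, 3)
    }
    trace <- data.frame(time_s = times, tgs822 = sig[, 1],
                        tgs813 = sig[, 2], mq3 = sig[, 3])
    trace <- new_sensor_trace(trace, run_id)

    t_off <- seq(0, config$duration, by = config$offline_interval)
    kin_off <- kinetics(config, t_off)
    ph <- kin_off$ph + stats::rnorm(length(t_off), 0, config$offline_ph_sd)
    tta <- kin_off$tta + stats::rnorm(length(t_off), 0, config$offline_tta_sd)
    tta <- pmax(tta, 0)
    offline <- new_offline_series(
      data.frame(time_h = t_off, ph = ph, tta = tta), run_id)

    truth <- kin
    names(truth) <- c("time_h", "ph_true", "tta_true", "activity")
    ferm_run(trace = trace, offline = offline, truth = truth,
             config = config, run_id = run_id)
  })
}

#' Bundle a trace and an offline series into a fermentation run
#'
#' @param trace A sensor trace (see [read_trace()] / [simulate_run()]).
#' @param offline An offline pH/TTA series.
#' @param truth Optional ground-truth grid (simulated runs only).
#' @param config Optional [sim_config()].
#' @param run_id Run identifier.
#' @return An object of class \code{ferm_run}.
#' @export
ferm_run <- function(trace, offline, truth = NULL, config = NULL,
                     run_id = "run1") {
  structure(list(trace = trace, offline = offline, truth = truth,
                 config = config, run_id = run_id),
            class = "ferm_run")
}

#' @export
print.ferm_run <- function(x, ...) {
  cat(sprintf("<ferm_run> %s: %d raw samples, %d offline samples\n",
              x$run_id, nrow(x$trace), nrow(x$offline)))
  invisible(x)
}

#' Read / write a simulation configuration file
#'
#' Flat key/value text file (YAML syntax) mirroring the [sim_config()]
#' arguments; \code{gap_spec} is a list of two-element \code{[start_h, end_h]}
#' vectors.
#'
#' @param path File path.
#' @return \code{read_sim_config()} returns a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$gap_spec)) {
    vals$gap_spec <- lapply(vals$gap_spec, as.numeric)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A \code{sim_config} to serialise.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
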