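# End-to-end campaigns: simulate (or load) a set of fermentation runs,
# extract features, fit the three calibration methods per run and per pooled
# group, evaluate on the 5-minute grid, and transfer-validate named
# TARGET-with-SOURCE pairs. Deterministic given the global seed.

#' Campaign configuration
#'
#' @param runs Named list of [sim_config()] objects (or \code{ferm_run}
#'   objects for pre-existing data), one per fermentation; names are run ids.
#' @param methods Calibration methods to fit: subset of
#'   \code{c("signal", "pca", "interval")}.
#' @param targets Subset of \code{c("ph", "tta")}.
#' @param feature_kind Feature for the sensor-signal method
#'   (\code{"height"} or \code{"area"}).
#' @param pools Named list of character vectors of run ids: grouped
#'   calibrations fitted on the pooled data of the member runs.
#' @param validations List of \code{c(target = id, source = id)} pairs (run or
#'   pool ids); read "TARGET with SOURCE".
#' @param seed Global integer seed; per-run seeds are derived from it by a
#'   stable hash of the run id.
#' @param interval_L Resample count for the interval method.
#' @return A \code{campaign_config}.
#' @export
campaign_config <- function(runs, methods = c("signal", "pca", "interval"),
                            targets = c("ph", "tta"),
                            feature_kind = "height",
                            pools = list(), validations = list(),
                            seed = 1L, interval_L = 60) {
  if (!length(runs)) stop("campaign must contain at least one run")
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    stop("runs must be a named list (names are run ids)")
  }
  if (anyDuplicated(names(runs))) stop("run ids must be unique")
  methods <- match.arg(methods, several.ok = TRUE)
  targets <- match.arg(targets, several.ok = TRUE)
  all_ids <- c(names(runs), names(pools))
  for (nm in names(pools)) {
    bad <- setdiff(pools[[nm]], names(runs))
    if (length(bad)) {
      stop(sprintf("pool '%s' references unknown run(s): %s", nm,
                   paste(bad, collapse = ", ")))
    }
  }
  for (v in validations) {
    bad <- setdiff(c(v[["target"]], v[["source"]]), all_ids)
    if (length(bad)) {
      stop(sprintf("validation references unknown id(s): %s",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(runs = runs, methods = methods, targets = targets,
                 feature_kind = feature_kind, pools = pools,
                 validations = validations, seed = as.integer(seed),
                 interval_L = interval_L),
            class = "campaign_config")
}

# Stable 31-bit hash of a run id, mixed with the global seed, so each run gets
# a reproducible independent RNG stream.
derive_seed <- function(global_seed, run_id) {
  h <- 0
  for (code in utf8ToInt(run_id)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (global_seed %% 65536) * 32749) %% 2147483647)
}

#' Sixteen-run experimental design
#'
#' Builds the campaign of a three-flour study: each flour fermented twice at
#' 28 deg C and twice at 32 deg C plus one 30 deg C validation run, all at
#' DY 200 — sixteen runs (one flour gets a third 28 deg C run). Flour-specific
#' kinetic parameters reflect wholegrain flour starting at higher pH and TTA
#' than the white flours. Pools group the same-temperature runs of each flour
#' and one cross-temperature combination per flour; validations insert each
#' grouped model into its flour's 30 deg C run.
#'
#' @param seed Global campaign seed.
#' @param duration Run length (h).
#' @param ... Further arguments to [campaign_config()].
#' @return A \code{campaign_config} with runs F1..F16.
#' @export
table2_design <- function(seed = 1L, duration = 10, ...) {
  plan <- data.frame(
    id = paste0("F", 1:16),
    temp = c(28, 32, 30, 28, 32, 28, 32, 28, 32, 28, 30, 32, 28, 32, 28, 30),
    flour = c("A", "A", "A", "A", "A", "A", "B", "B", "B", "B", "B",
              "C", "C", "C", "C", "C"))
  kin <- list(
    A = list(pH0 = 6.0, pH_inf = 3.8, TTA0 = 7.0, TTA_slope_ref = 0.8),
    B = list(pH0 = 5.6, pH_inf = 3.6, TTA0 = 5.0, TTA_slope_ref = 0.7),
    C = list(pH0 = 5.7, pH_inf = 3.6, TTA0 = 5.5, TTA_slope_ref = 0.65))
  runs <- lapply(seq_len(nrow(plan)), function(i) {
    k <- kin[[plan$flour[i]]]
    sim_config(duration = duration, temperature = plan$temp[i],
               flour_label = plan$flour[i], pH0 = k$pH0, pH_inf = k$pH_inf,
               TTA0 = k$TTA0, TTA_slope_ref = k$TTA_slope_ref)
  })
  names(runs) <- plan$id
  pools <- list(
    A_28C = c("F1", "F4"), A_32C = c("F2", "F5"), A_star = c("F2", "F6"),
    B_28C = c("F8", "F10"), B_32C = c("F7", "F9"), B_star = c("F7", "F10"),
    C_28C = c("F13", "F15"), C_32C = c("F12", "F14"), C_star = c("F13", "F16"))
  validations <- list(
    c(target = "F3", source = "A_28C"), c(target = "F3", source = "A_32C"),
    c(target = "F3", source = "A_star"),
    c(target = "F11", source = "B_28C"), c(target = "F11", source = "B_32C"),
    c(target = "F11", source = "B_star"),
    c(target = "F16", source = "C_28C"), c(target = "F16", source = "C_32C"))
  campaign_config(runs, pools = pools, validations = validations,
                  seed = seed, ...)
}

fit_method <- function(method, data, target, cc) {
  switch(method,
         signal = fit_sensor_signal(data, target = target,
                                    feature_kind = cc$feature_kind),
         pca = fit_pca_regression(data, target = target),
         interval = fit_interval_pca(data, target = target,
                                     L = cc$interval_L))
}

#' Run an end-to-end campaign
#'
#' Simulates every configured run with a seed derived from the global seed,
#' writes per-run trace/offline/feature CSVs and model files under
#' \code{out_dir}, fits every (run and pool) x method x target calibration,
#' evaluates each on its own 5-minute grid, performs the configured transfer
#' validations, and writes \code{metrics.csv} and \code{validations.csv}.
#' Rerunning with the same configuration reproduces every output exactly.
#'
#' @param cc A [campaign_config()].
#' @param out_dir Output directory (created if absent). \code{NULL} skips all
#'   file output and returns the tables only.
#' @param write_raw Also write the (large) raw trace CSVs?
#' @return Invisibly, a list with data.frames \code{metrics} and
#'   \code{validations}, the fitted \code{models}, and the simulated
#'   \code{runs}.
#' @export
run_campaign <- function(cc, out_dir = NULL, write_raw = FALSE) {
  stopifnot(inherits(cc, "campaign_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  runs <- list()
  for (id in names(cc$runs)) {
    spec <- cc$runs[[id]]
    if (inherits(spec, "ferm_run")) {
      runs[[id]] <- spec
    } else {
      spec$seed <- derive_seed(cc$seed, id)
      runs[[id]] <- simulate_run(spec, run_id = id)
    }
    runs[[id]]$features <- build_feature_table(runs[[id]]$trace,
                                               cadence = spec$cadence %||% 300)
    if (!is.null(out_dir)) {
      rd <- file.path(out_dir, "runs", id)
      dir.create(rd, recursive = TRUE, showWarnings = FALSE)
      if (write_raw) write_trace(runs[[id]]$trace, file.path(rd, "trace.csv"))
      write_offline(runs[[id]]$offline, file.path(rd, "offline.csv"))
      write_features(runs[[id]]$features, file.path(rd, "features.csv"))
    }
  }
  datasets <- c(runs, lapply(cc$pools, function(ids) pool_runs(runs[ids])))

  models <- list()
  metrics <- list()
  for (ds_id in names(datasets)) {
    for (method in cc$methods) {
      for (target in cc$targets) {
        model <- fit_method(method, datasets[[ds_id]], target, cc)
        key <- paste(ds_id, method, target, sep = ".")
        models[[key]] <- model
        met <- evaluate_calibration(model, datasets[[ds_id]],
                                    r2 = (method == "signal"))
        metrics[[key]] <- data.frame(
          run = ds_id, method = method, target = target,
          feature = if (method == "signal") cc$feature_kind else NA,
          n = met$n, sse = met$sse, rmse = met$rmse,
          pct_error = met$pct_error, r2 = met$r2 %||% NA_real_)
        if (!is.null(out_dir)) {
          md <- file.path(out_dir, "models")
          dir.create(md, showWarnings = FALSE)
          save_model(model, file.path(md, paste0(key, ".json")))
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  validations <- list()
  for (v in cc$validations) {
    for (method in cc$methods) {
      for (target in cc$targets) {
        key <- paste(v[["source"]], method, target, sep = ".")
        vr <- transfer_validate(models[[key]], datasets[[v[["target"]]]],
                                label = sprintf("%s with %s", v[["target"]],
                                                v[["source"]]))
        validations[[length(validations) + 1]] <- data.frame(
          validation = vr$label, method = method, target = target,
          n = vr$metrics$n, sse = vr$metrics$sse, rmse = vr$metrics$rmse,
          pct_error = vr$metrics$pct_error)
      }
    }
  }
  validations <- if (length(validations)) {
    do.call(rbind, validations)
  } else {
    data.frame(validation = character(0), method = character(0),
               target = character(0), n = integer(0), sse = numeric(0),
               rmse = numeric(0), pct_error = numeric(0))
  }
  rownames(validations) <- NULL

  if (!is.null(out_dir)) {
    utils::write.csv(format_metric_table(metrics),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(format_metric_table(validations),
                     file.path(out_dir, "validations.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(list(metrics = metrics, validations = validations,
                 models = models, runs = runs))
}

format_metric_table <- function(df) {
  for (cl in intersect(c("sse", "rmse", "pct_error", "r2"), names(df))) {
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  df
}
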