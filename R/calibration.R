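# The three calibration methods mapping gas-sensor information to pH or TTA:
#
#   signal   C = K1 + K2 (PH_822 - BL) + K3 (PH_813 - BL) + K4 (PH_MQ3 - BL)
#            (peak-area variant uses PA - BL*cadence as the regressor)
#   pca      C = K9 + K10 PC1 + K11 PC2, scores from an autoscaled PCA of the
#            six peak features
#   interval C = K1 + K2 PC1, scores from a mean-centred PCA of the resampled
#            raw cycle shapes (3 channels x L points per cycle)
#
# All coefficient vectors are the exact least-squares minimisers of the sum of
# squared errors over the fitted pairs.

FEATURE6 <- c("ph_tgs822", "pa_tgs822", "ph_tgs813", "pa_tgs813",
              "ph_mq3", "pa_mq3")

# Canonical internal form: a list of per-run records with elements
# run_id, features (feature_table or NULL), offline, trace (or NULL).
as_run_records <- function(x, offline = NULL, cadence = 300, ...) {
  if (inherits(x, "ferm_pool")) {
    ids <- vapply(x, function(r) r$run_id, "")
    if (anyDuplicated(ids)) ids <- paste0(ids, "#", seq_along(ids))
    return(lapply(seq_along(x), function(i) {
      r <- x[[i]]
      list(run_id = ids[i], features = r$features,
           offline = r$offline, trace = r$trace)
    }))
  }
  if (inherits(x, "ferm_run")) {
    return(list(list(run_id = x$run_id, features = x$features,
                     offline = x$offline, trace = x$trace)))
  }
  if (inherits(x, "feature_table")) {
    if (is.null(offline)) stop("offline series required with a feature table")
    return(list(list(run_id = attr(x, "run_id") %||% "run1", features = x,
                     offline = offline, trace = NULL)))
  }
  if (inherits(x, "sensor_trace")) {
    if (is.null(offline)) stop("offline series required with a sensor trace")
    return(list(list(run_id = attr(x, "run_id") %||% "run1", features = NULL,
                     offline = offline, trace = x)))
  }
  stop("x must be a ferm_run, ferm_pool, feature_table or sensor_trace")
}

record_features <- function(rec, cadence, ...) {
  if (!is.null(rec$features)) return(rec$features)
  if (is.null(rec$trace)) stop("run carries neither features nor a raw trace")
  build_feature_table(rec$trace, cadence = cadence, ...)
}

#' Pool several fermentation runs
#'
#' Grouped calibrations (e.g. the two 28 deg C runs of one flour, or the
#' "A*"-style cross-temperature combinations) are fitted on pooled data: the
#' feature/interval rows of all member runs are treated jointly, with one
#' shared autoscaling/PCA basis and one coefficient vector.
#'
#' @param runs A list of \code{ferm_run} objects (or a single run).
#' @return An object of class \code{ferm_pool}.
#' @export
pool_runs <- function(runs) {
  if (inherits(runs, "ferm_run")) runs <- list(runs)
  if (!length(runs) || !all(vapply(runs, inherits, logical(1), "ferm_run"))) {
    stop("runs must be a non-empty list of ferm_run objects")
  }
  cads <- unlist(lapply(runs, function(r) {
    if (!is.null(r$config)) r$config$cadence
    else if (!is.null(r$features)) attr(r$features, "cadence") else NULL
  }))
  if (length(unique(cads)) > 1) {
    stop(sprintf("cadence mismatch across pooled runs: %s",
                 paste(unique(cads), collapse = ", ")))
  }
  structure(runs, class = "ferm_pool")
}

#' @export
print.ferm_pool <- function(x, ...) {
  cat(sprintf("<ferm_pool> %d runs: %s\n", length(x),
              paste(vapply(x, function(r) r$run_id, ""), collapse = ", ")))
  invisible(x)
}

#' Match offline samples to feature-table rows
#'
#' Each offline sample is paired with the feature row whose interval midpoint
#' is nearest in time (ties broken toward the earlier interval). Samples
#' farther than \code{cadence/2 + tolerance} from any retained interval — for
#' instance inside an acquisition gap — are dropped with a warning.
#'
#' @param features A \code{feature_table}.
#' @param offline An \code{offline_series} of the same run.
#' @param cadence Cycle length (s); defaults to the table's attribute.
#' @param tolerance Extra matching slack in seconds.
#' @return A data.frame of paired rows: offline \code{time_h}, \code{ph},
#'   \code{tta}, plus all matched feature columns.
#' @export
match_offline <- function(features, offline, cadence = NULL, tolerance = 0) {
  stopifnot(inherits(features, "feature_table"), nrow(features) > 0,
            nrow(offline) > 0)
  cadence <- cadence %||% attr(features, "cadence") %||% 300
  t_off <- offline$time_h * 3600
  j <- integer(0); keep <- integer(0)
  for (i in seq_along(t_off)) {
    d <- abs(features$t_mid_s - t_off[i])
    jj <- which.min(d)  # first minimum = earlier interval on ties
    if (d[jj] <= cadence / 2 + tolerance) {
      j <- c(j, jj); keep <- c(keep, i)
    }
  }
  if (length(keep) < length(t_off)) {
    warning(sprintf("dropped %d offline sample(s) with no matching interval (t_h = %s)",
                    length(t_off) - length(keep),
                    paste(offline$time_h[setdiff(seq_along(t_off), keep)],
                          collapse = ", ")))
  }
  if (!length(keep)) stop("no offline sample matches any retained interval")
  cbind(offline[keep, c("time_h", "ph", "tta"), drop = FALSE],
        as.data.frame(features)[j, , drop = FALSE],
        row.names = NULL)
}

# Baseline-corrected regressor matrix for the sensor-signal method.
signal_design <- function(rows, feature_kind, cadence) {
  if (feature_kind == "height") {
    X <- cbind(rows$ph_tgs822 - rows$bl_tgs822,
               rows$ph_tgs813 - rows$bl_tgs813,
               rows$ph_mq3 - rows$bl_mq3)
  } else {
    X <- cbind(rows$pa_tgs822 - rows$bl_tgs822 * cadence,
               rows$pa_tgs813 - rows$bl_tgs813 * cadence,
               rows$pa_mq3 - rows$bl_mq3 * cadence)
  }
  colnames(X) <- CHANNELS
  X
}

ols_fit <- function(X, y, names_out) {
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop(sprintf("rank-deficient design; collinear regressor(s): %s",
                 paste(bad, collapse = ", ")))
  }
  names(cf) <- names_out
  list(coefficients = cf, sse = sum(stats::residuals(fit)^2))
}

matched_pairs <- function(records, target, cadence, tolerance, ...) {
  do.call(rbind, lapply(records, function(rec) {
    ft <- record_features(rec, cadence, ...)
    m <- match_offline(ft, rec$offline, cadence, tolerance)
    m$run <- rec$run_id
    m
  }))
}

#' Fit the sensor-signal calibration
#'
#' Ordinary least squares on the baseline-corrected peak features at the
#' offline-matched intervals: \eqn{C = K_1 + \sum_c K_c (PH_c - BL_c)} (or the
#' peak-area analogue). OLS is the exact minimiser of the sum of squared
#' errors over the matched pairs.
#'
#' @param x A \code{ferm_run}, \code{ferm_pool}, or \code{feature_table}.
#' @param offline Offline series (only when \code{x} is a bare feature table).
#' @param target \code{"ph"} or \code{"tta"}.
#' @param feature_kind \code{"height"} (peak height) or \code{"area"}.
#' @param cadence Cycle length (s).
#' @param tolerance Offline-matching slack (s).
#' @param ... Feature-extraction options passed to [build_feature_table()].
#' @return A \code{gsa_signal_model}.
#' @export
fit_sensor_signal <- function(x, offline = NULL, target = c("ph", "tta"),
                              feature_kind = c("height", "area"),
                              cadence = 300, tolerance = 0, ...) {
  target <- match.arg(target)
  feature_kind <- match.arg(feature_kind)
  records <- as_run_records(x, offline)
  m <- matched_pairs(records, target, cadence, tolerance, ...)
  if (nrow(m) < 5) stop("need at least 5 matched offline/feature pairs")
  X <- signal_design(m, feature_kind, cadence)
  fit <- ols_fit(X, m[[target]], c("intercept", CHANNELS))
  structure(list(target = target, feature_kind = feature_kind,
                 coefficients = fit$coefficients, cadence = cadence,
                 n = nrow(m), sse_fit = fit$sse,
                 run_ids = unique(m$run)),
            class = c("gsa_signal_model", "ferm_model"))
}

# Autoscaling + first-two-axes PCA of the six-feature matrix. Scaling uses
# the population (denominator-n) standard deviation so that duplicating every
# row leaves the basis, the scores and hence the regression coefficients
# exactly unchanged. Zero-variance features are dropped before scaling
# (loadings padded with 0). Axis signs are fixed so the largest-magnitude
# loading entry is positive.
pca6_fit <- function(M) {
  center <- colMeans(M)
  sds <- sqrt(colMeans(sweep(M, 2, center)^2))
  kept <- sds > 1e-12
  if (any(!kept)) {
    warning(sprintf("zero-variance feature(s) dropped before scaling: %s",
                    paste(FEATURE6[!kept], collapse = ", ")))
  }
  if (sum(kept) < 2) stop("fewer than 2 informative feature directions")
  scale <- ifelse(kept, sds, 1)
  Z <- sweep(sweep(M[, kept, drop = FALSE], 2, center[kept]), 2, scale[kept], "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("fewer than 2 informative feature directions")
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  rot <- fix_axis_signs(rot)
  loadings <- matrix(0, length(FEATURE6), 2,
                     dimnames = list(FEATURE6, c("PC1", "PC2")))
  loadings[kept, ] <- rot
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(center = center, scale = scale, loadings = loadings,
       explained_var = ev[1:2])
}

fix_axis_signs <- function(rot) {
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  rot
}

pca6_scores <- function(M, model) {
  Z <- sweep(sweep(M, 2, model$center), 2, model$scale, "/")
  Z %*% model$loadings
}

feature6_matrix <- function(features) {
  as.matrix(as.data.frame(features)[, FEATURE6])
}

#' Fit the PCA-regression calibration
#'
#' The six peak features are autoscaled (centred, unit variance) over all
#' retained intervals of the fitted dataset and projected on the first two
#' principal axes; the regression \eqn{C = K_9 + K_{10} PC1 + K_{11} PC2} is
#' then fitted by least squares on the offline-matched rows. Setting
#' \code{fit_rows = "matched"} restricts the PCA itself to the matched rows.
#'
#' @inheritParams fit_sensor_signal
#' @param fit_rows Rows used for the PCA basis: \code{"all"} retained
#'   intervals (default) or only the offline-\code{"matched"} rows.
#' @return A \code{gsa_pca_model}.
#' @export
fit_pca_regression <- function(x, offline = NULL, target = c("ph", "tta"),
                               fit_rows = c("all", "matched"),
                               cadence = 300, tolerance = 0, ...) {
  target <- match.arg(target)
  fit_rows <- match.arg(fit_rows)
  records <- as_run_records(x, offline)
  fts <- lapply(records, record_features, cadence = cadence, ...)
  m <- do.call(rbind, lapply(seq_along(records), function(i) {
    mm <- match_offline(fts[[i]], records[[i]]$offline, cadence, tolerance)
    mm$run <- records[[i]]$run_id
    mm
  }))
  if (nrow(m) < 4) stop("need at least 4 matched offline/feature pairs")
  M_basis <- if (fit_rows == "all") {
    do.call(rbind, lapply(fts, feature6_matrix))
  } else {
    as.matrix(m[, FEATURE6])
  }
  basis <- pca6_fit(M_basis)
  S <- pca6_scores(as.matrix(m[, FEATURE6]), basis)
  fit <- ols_fit(S, m[[target]], c("intercept", "pc1", "pc2"))
  structure(list(target = target, center = basis$center, scale = basis$scale,
                 loadings = basis$loadings,
                 explained_var = basis$explained_var,
                 coefficients = fit$coefficients, cadence = cadence,
                 fit_rows = fit_rows, n = nrow(m), sse_fit = fit$sse,
                 run_ids = unique(m$run)),
            class = c("gsa_pca_model", "ferm_model"))
}

# Resample each channel of a segment to L points by linear interpolation and
# concatenate to one 3L shape vector.
resample_segment <- function(seg, L) {
  grid <- seq(seg$time_s[1], seg$time_s[length(seg$time_s)], length.out = L)
  unlist(lapply(seq_len(ncol(seg$channels)), function(i) {
    stats::approx(seg$time_s, seg$channels[, i], xout = grid)$y
  }), use.names = FALSE)
}

interval_matrix <- function(records, L, cadence, tolerance, min_samples) {
  rows <- list(); t_mid <- numeric(0); run <- character(0)
  for (rec in records) {
    if (is.null(rec$trace)) {
      stop("the interval method needs the raw trace of every run")
    }
    segs <- segment_intervals(rec$trace, cadence, tolerance, min_samples)
    for (s in segs) {
      rows[[length(rows) + 1]] <- resample_segment(s, L)
      t_mid <- c(t_mid, (s$t_start + s$t_end) / 2)
      run <- c(run, rec$run_id)
    }
  }
  if (!length(rows)) stop("no retained intervals in any trace")
  list(V = do.call(rbind, rows), t_mid = t_mid, run = run)
}

interval_axis_fit <- function(V) {
  center <- colMeans(V)
  Vc <- sweep(V, 2, center)
  pc <- stats::prcomp(Vc, center = FALSE, scale. = FALSE)
  if (pc$sdev[1] < 1e-12) stop("degenerate score variance: all intervals identical")
  loading <- pc$rotation[, 1]
  imax <- which.max(abs(loading))
  if (loading[imax] < 0) loading <- -loading
  list(center = center, loading = loading,
       explained_variance_1 = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Fit the interval-PCA calibration
#'
#' The raw samples of every retained 5-minute cycle are resampled to \code{L}
#' points per channel, concatenated to a 3L shape vector, and the matrix of
#' cycle shapes is mean-centred and projected on its first principal axis —
#' one score per cycle. The offline target is linearly interpolated to the
#' cycle midpoints (constant beyond the sampled span) and
#' \eqn{C = K_1 + K_2 PC1} is fitted by least squares over all cycles. Only
#' the first component is used: on pulse-shaped cycles it typically explains
#' essentially all shape variance, and further components mostly add noise
#' (\code{n_components} is exposed for diagnostics but predictions use PC1).
#'
#' @inheritParams fit_sensor_signal
#' @param L Resample count per channel (shape vector length is 3L).
#' @param min_samples Minimum samples per retained segment.
#' @return A \code{gsa_interval_model} with the explained variance of the
#'   first axis in \code{$explained_variance_1}.
#' @export
fit_interval_pca <- function(x, offline = NULL, target = c("ph", "tta"),
                             L = 60, cadence = 300, tolerance = cadence / 10,
                             min_samples = 20) {
  target <- match.arg(target)
  records <- as_run_records(x, offline)
  im <- interval_matrix(records, L, cadence, tolerance, min_samples)
  if (nrow(im$V) < 3) stop("need at least 3 retained intervals")
  axis <- interval_axis_fit(im$V)
  scores <- as.vector(sweep(im$V, 2, axis$center) %*% axis$loading)
  if (stats::sd(scores) < 1e-12) stop("degenerate score variance")
  y <- interval_targets(records, im, target)
  fit <- ols_fit(matrix(scores, ncol = 1, dimnames = list(NULL, "pc1")),
                 y, c("intercept", "slope"))
  structure(list(target = target, L = L, center = axis$center,
                 loading = axis$loading,
                 explained_variance_1 = axis$explained_variance_1,
                 coefficients = fit$coefficients, cadence = cadence,
                 min_samples = min_samples, n = length(y), sse_fit = fit$sse,
                 run_ids = unique(im$run)),
            class = c("gsa_interval_model", "ferm_model"))
}

interval_targets <- function(records, im, target) {
  y <- numeric(length(im$t_mid))
  for (rec in records) {
    sel <- im$run == rec$run_id
    y[sel] <- stats::approx(rec$offline$time_h * 3600, rec$offline[[target]],
                            xout = im$t_mid[sel], rule = 2)$y
  }
  y
}

#' @export
print.ferm_model <- function(x, ...) {
  cat(sprintf("<%s> target %s, n = %d, fit SSE = %.4g\n",
              class(x)[1], x$target, x$n, x$sse_fit))
  cat("coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

new_prediction_series <- function(run, interval, t_mid_s, value, model) {
  structure(data.frame(run = run, interval = interval, t_mid_s = t_mid_s,
                       value = value),
            target = model$target, method = model_method_tag(model),
            class = c("prediction_series", "data.frame"))
}

predict_signal_rows <- function(object, features) {
  X <- signal_design(features, object$feature_kind, object$cadence)
  as.vector(object$coefficients[1] + X %*% object$coefficients[-1])
}

#' Predict pH or TTA on the 5-minute grid
#'
#' Applies a fitted model's stored transformation (baseline subtraction,
#' autoscale-and-project, or resample-centre-project) and linear equation at
#' every retained interval of the input.
#'
#' @param object A fitted calibration model.
#' @param newdata A \code{ferm_run}/\code{ferm_pool}; the sensor-signal and
#'   PCA methods also accept a bare \code{feature_table}, the interval method
#'   a bare \code{sensor_trace}.
#' @param ... Feature-extraction options.
#' @return A \code{prediction_series} data.frame with columns \code{run},
#'   \code{interval}, \code{t_mid_s}, \code{value}.
#' @export
predict.gsa_signal_model <- function(object, newdata, ...) {
  ft_records <- prediction_records(object, newdata, need_trace = FALSE, ...)
  do.call(rbind_predictions, lapply(ft_records, function(rec) {
    new_prediction_series(rec$run_id, rec$features$interval,
                          rec$features$t_mid_s,
                          predict_signal_rows(object, rec$features), object)
  }))
}

#' @rdname predict.gsa_signal_model
#' @export
predict.gsa_pca_model <- function(object, newdata, ...) {
  ft_records <- prediction_records(object, newdata, need_trace = FALSE, ...)
  do.call(rbind_predictions, lapply(ft_records, function(rec) {
    S <- pca6_scores(feature6_matrix(rec$features), object)
    val <- as.vector(object$coefficients[1] + S %*% object$coefficients[-1])
    new_prediction_series(rec$run_id, rec$features$interval,
                          rec$features$t_mid_s, val, object)
  }))
}

#' @rdname predict.gsa_signal_model
#' @export
predict.gsa_interval_model <- function(object, newdata, ...) {
  records <- if (inherits(newdata, "sensor_trace")) {
    list(list(run_id = attr(newdata, "run_id") %||% "run1", trace = newdata))
  } else if (inherits(newdata, "ferm_run")) {
    list(list(run_id = newdata$run_id, trace = newdata$trace))
  } else if (inherits(newdata, "ferm_pool")) {
    lapply(newdata, function(r) list(run_id = r$run_id, trace = r$trace))
  } else {
    stop("the interval method predicts from raw traces, not feature tables")
  }
  im <- interval_matrix(records, object$L, object$cadence,
                        object$cadence / 10, object$min_samples %||% 20)
  scores <- as.vector(sweep(im$V, 2, object$center) %*% object$loading)
  val <- object$coefficients[1] + object$coefficients[2] * scores
  idx <- round(im$t_mid / object$cadence - 0.5)
  new_prediction_series(im$run, idx, im$t_mid, val, object)
}

prediction_records <- function(object, newdata, need_trace, ...) {
  if (inherits(newdata, "feature_table")) {
    return(list(list(run_id = attr(newdata, "run_id") %||% "run1",
                     features = newdata)))
  }
  if (inherits(newdata, "ferm_run")) newdata <- list(newdata)
  if (inherits(newdata, "ferm_pool") || is.list(newdata)) {
    return(lapply(newdata, function(r) {
      list(run_id = r$run_id,
           features = r$features %||%
             build_feature_table(r$trace, cadence = object$cadence, ...))
    }))
  }
  stop("newdata must be a feature_table, ferm_run or ferm_pool")
}

rbind_predictions <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  attr(out, "target") <- attr(parts[[1]], "target")
  attr(out, "method") <- attr(parts[[1]], "method")
  class(out) <- c("prediction_series", "data.frame")
  out
}
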