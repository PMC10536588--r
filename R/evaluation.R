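# Error metrics on the 5-minute evaluation grid and parameter-transfer
# validation between calibration models. A 10 h gap-free run yields the
# nominal 120-point evaluation vector; acquisition gaps reduce n.

#' Reference values on the evaluation grid
#'
#' Interpolates the hourly offline measurements linearly onto the 5-minute
#' interval grid; beyond the first/last offline sample the value is held
#' constant. One reference point per retained interval feeds the error
#' calculation.
#'
#' @param offline An \code{offline_series}.
#' @param grid_s Interval times in seconds (typically cycle midpoints).
#' @param target \code{"ph"} or \code{"tta"}.
#' @return Numeric vector of references, one per grid point.
#' @export
reference_series <- function(offline, grid_s, target = c("ph", "tta")) {
  target <- match.arg(target)
  if (!length(grid_s)) stop("empty evaluation grid")
  if (nrow(offline) < 2) stop("offline series must span at least 2 samples")
  stats::approx(offline$time_h * 3600, offline[[target]],
                xout = grid_s, rule = 2)$y
}

#' Prediction error metrics
#'
#' The standard chemometric error triple on the evaluation grid:
#' \eqn{SSE = \sum (pred - ref)^2}, \eqn{RMSE = \sqrt{SSE/n}}, and the
#' percentage error \eqn{100\, RMSE / (\max ref - \min ref)} that adjusts the
#' error to the range of reference values (making pH and TTA models
#' comparable). Optionally the \eqn{R^2} of predicted vs measured.
#'
#' @param pred A \code{prediction_series} or numeric vector of predictions.
#' @param ref Numeric vector of reference values, aligned with \code{pred}.
#' @param r2 Also compute [r_squared()]?
#' @return A \code{ferm_metrics} list: \code{n}, \code{sse}, \code{rmse},
#'   \code{pct_error}, and \code{r2} when requested.
#' @export
score_predictions <- function(pred, ref, r2 = FALSE) {
  p <- if (inherits(pred, "prediction_series")) pred$value else as.numeric(pred)
  if (length(p) != length(ref)) stop("pred and ref must be aligned")
  n <- length(p)
  if (n < 2) stop("need at least 2 evaluated grid points")
  sse <- sum((p - ref)^2)
  rmse <- sqrt(sse / n)
  rng <- max(ref) - min(ref)
  pct <- if (rng > 0) 100 * rmse / rng else {
    warning("zero reference range: pct_error undefined")
    NA_real_
  }
  out <- list(n = n, sse = sse, rmse = rmse, pct_error = pct)
  if (r2) out$r2 <- r_squared(p, ref)
  structure(out, class = "ferm_metrics")
}

#' @export
print.ferm_metrics <- function(x, ...) {
  cat(sprintf("n = %d, SSE = %.4g, RMSE = %.4g, %%error = %.3g%s\n",
              x$n, x$sse, x$rmse, x$pct_error,
              if (!is.null(x$r2)) sprintf(", R2 = %.4g", x$r2) else ""))
  invisible(x)
}

#' Coefficient of determination of predicted vs measured
#'
#' R-squared of the least-squares line through the (measured, predicted)
#' pairs — the squared Pearson correlation. For the PCA-based methods the
#' scatter of the scores makes this a weaker diagnostic than for the
#' sensor-signal method; it is reported with a warning rather than suppressed.
#'
#' @param pred,ref Aligned numeric vectors (a \code{prediction_series} is
#'   accepted for \code{pred}).
#' @return R-squared in \[0, 1\], or NA (with a warning) if either series has
#'   zero variance.
#' @export
r_squared <- function(pred, ref) {
  p <- if (inherits(pred, "prediction_series")) pred$value else as.numeric(pred)
  if (length(p) < 3) stop("need at least 3 points for R2")
  if (stats::sd(p) < 1e-300 || stats::sd(ref) < 1e-300) {
    warning("zero variance: R2 undefined")
    return(NA_real_)
  }
  stats::cor(p, ref)^2
}

# Reference vector aligned with a prediction series, looked up per run.
aligned_reference <- function(pred, data, target) {
  records <- as_run_records(data)
  ref <- numeric(nrow(pred))
  for (rec in records) {
    sel <- pred$run == rec$run_id
    if (!any(sel)) next
    ref[sel] <- reference_series(rec$offline, pred$t_mid_s[sel], target)
  }
  ref
}

#' Evaluate a calibration on a dataset
#'
#' Predicts at every retained interval of \code{data}, interpolates the
#' offline target onto the same grid, and scores the pair.
#'
#' @param model A fitted calibration model.
#' @param data A \code{ferm_run} or \code{ferm_pool} (must carry the offline
#'   series).
#' @param r2 Also compute R-squared?
#' @param ... Passed to the predict method.
#' @return A \code{ferm_metrics} object.
#' @export
evaluate_calibration <- function(model, data, r2 = FALSE, ...) {
  pred <- stats::predict(model, data, ...)
  ref <- aligned_reference(pred, data, model$target)
  score_predictions(pred, ref, r2 = r2)
}

#' Transfer-validate a calibration on another dataset
#'
#' Portability check in the "TARGET with SOURCE" sense: the coefficients of a
#' model fitted on one dataset (the source) are inserted into the regression
#' equation of another dataset (the target), and the resulting predictions
#' are scored against the target's own reference series. With
#' \code{basis = "target"} (default) the target dataset's own transformation
#' is used — its own baselines and, for the PCA-based methods, a PCA refitted
#' on the target — and only the coefficients come from the source. With
#' \code{basis = "source"} the source model's stored transformation is applied
#' to the target data unchanged.
#'
#' @param source_model A fitted calibration model.
#' @param target_data A \code{ferm_run} or \code{ferm_pool}.
#' @param basis \code{"target"} or \code{"source"} transformation basis.
#' @param label Report label; defaults to "TARGET with SOURCE" run ids.
#' @param r2 Also compute R-squared?
#' @param ... Feature-extraction options.
#' @return A \code{validation_report}: list with \code{label}, \code{source},
#'   \code{target}, \code{basis}, \code{metrics}.
#' @export
transfer_validate <- function(source_model, target_data,
                              basis = c("target", "source"),
                              label = NULL, r2 = FALSE, ...) {
  basis <- match.arg(basis)
  if (!inherits(source_model, "ferm_model")) stop("source_model must be fitted")
  method <- model_method_tag(source_model)
  pred <- if (basis == "source" || method == "signal") {
    stats::predict(source_model, target_data, ...)
  } else if (method == "pca") {
    records <- as_run_records(target_data)
    fts <- lapply(records, record_features, cadence = source_model$cadence, ...)
    basis_rows <- if ((source_model$fit_rows %||% "all") == "matched") {
      do.call(rbind, lapply(seq_along(records), function(i) {
        m <- match_offline(fts[[i]], records[[i]]$offline, source_model$cadence)
        as.matrix(m[, FEATURE6])
      }))
    } else {
      do.call(rbind, lapply(fts, feature6_matrix))
    }
    tgt_basis <- pca6_fit(basis_rows)
    do.call(rbind_predictions, lapply(seq_along(records), function(i) {
      S <- pca6_scores(feature6_matrix(fts[[i]]), tgt_basis)
      val <- as.vector(source_model$coefficients[1] +
                         S %*% source_model$coefficients[-1])
      new_prediction_series(records[[i]]$run_id, fts[[i]]$interval,
                            fts[[i]]$t_mid_s, val, source_model)
    }))
  } else { # interval method, target basis
    records <- as_run_records(target_data)
    im <- interval_matrix(records, source_model$L, source_model$cadence,
                          source_model$cadence / 10,
                          source_model$min_samples %||% 20)
    axis <- interval_axis_fit(im$V)
    scores <- as.vector(sweep(im$V, 2, axis$center) %*% axis$loading)
    val <- source_model$coefficients[1] + source_model$coefficients[2] * scores
    idx <- round(im$t_mid / source_model$cadence - 0.5)
    new_prediction_series(im$run, idx, im$t_mid, val, source_model)
  }
  ref <- aligned_reference(pred, target_data, source_model$target)
  metrics <- score_predictions(pred, ref, r2 = r2)
  target_id <- paste(vapply(as_run_records(target_data),
                            function(r) r$run_id, ""), collapse = "+")
  structure(list(label = label %||% sprintf("%s with %s", target_id,
                                            paste(source_model$run_ids,
                                                  collapse = "+")),
                 source = paste(source_model$run_ids, collapse = "+"),
                 target = target_id, basis = basis, metrics = metrics),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation> %s (basis: %s)\n  ", x$label, x$basis))
  print(x$metrics)
  invisible(x)
}
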