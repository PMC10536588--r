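# File formats: raw trace CSV (time_s,tgs822,tgs813,mq3), offline CSV
# (time_h,ph,tta), feature-table CSV, and JSON model files. All numeric
# columns are written with 17 significant digits so read(write(x)) is an
# identity at full double precision.

CHANNELS <- c("tgs822", "tgs813", "mq3")

fmt_num <- function(x) sprintf("%.17g", x)

# Parse a character column to numeric, reporting 1-based data row numbers of
# offending cells.
parse_numeric_col <- function(x, col, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) || anyNA(x) || any(!nzchar(trimws(x)))) {
    bad <- sort(unique(c(bad, which(is.na(x) | !nzchar(trimws(x))))))
    stop(sprintf("%s: non-numeric or missing value in column '%s' at row %s",
                 path, col, paste(bad, collapse = ", ")))
  }
  v
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) stop(sprintf("%s: no data rows", path))
  out <- as.data.frame(lapply(required, function(cl) {
    parse_numeric_col(df[[cl]], cl, path)
  }), col.names = required)
  out
}

#' Construct a sensor trace in memory
#'
#' Validating constructor for the raw three-channel signal of one run; the
#' same invariants are enforced as by [read_trace()].
#'
#' @param time_s Strictly increasing sample times in seconds.
#' @param tgs822,tgs813,mq3 Channel signal vectors (finite, same length).
#' @param run_id Run identifier.
#' @return A \code{sensor_trace} data.frame.
#' @export
sensor_trace <- function(time_s, tgs822, tgs813, mq3, run_id = "run1") {
  new_sensor_trace(data.frame(time_s = time_s, tgs822 = tgs822,
                              tgs813 = tgs813, mq3 = mq3), run_id)
}

#' Construct an offline pH/TTA series in memory
#'
#' @param time_h Strictly increasing sample times in hours.
#' @param ph pH values in (0, 14).
#' @param tta TTA values (mL 0.1 M NaOH per 10 g), non-negative.
#' @param run_id Run identifier.
#' @return An \code{offline_series} data.frame.
#' @export
offline_series <- function(time_h, ph, tta, run_id = "run1") {
  new_offline_series(data.frame(time_h = time_h, ph = ph, tta = tta), run_id)
}

new_sensor_trace <- function(df, run_id = "run1") {
  stopifnot(all(c("time_s", CHANNELS) %in% names(df)))
  if (any(!is.finite(as.matrix(df[c("time_s", CHANNELS)])))) {
    stop("sensor trace contains non-finite values")
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    stop(sprintf("trace time not strictly increasing at row %d", bad[1] + 1))
  }
  structure(df, run_id = run_id, class = c("sensor_trace", "data.frame"))
}

new_offline_series <- function(df, run_id = "run1") {
  stopifnot(all(c("time_h", "ph", "tta") %in% names(df)))
  bad <- which(diff(df$time_h) <= 0)
  if (length(bad)) {
    stop(sprintf("offline time not strictly increasing at row %d", bad[1] + 1))
  }
  badph <- which(df$ph <= 0 | df$ph >= 14)
  if (length(badph)) {
    stop(sprintf("offline pH outside (0, 14) at row %d", badph[1]))
  }
  badtta <- which(df$tta < 0)
  if (length(badtta)) {
    stop(sprintf("offline TTA negative at row %d", badtta[1]))
  }
  structure(df, run_id = run_id, class = c("offline_series", "data.frame"))
}

#' Read and write raw sensor traces
#'
#' CSV with header \code{time_s,tgs822,tgs813,mq3}, '.' decimal separator.
#' Time must be strictly increasing; rows with missing or non-numeric cells
#' are rejected with the offending row number. Values round-trip at full
#' double precision.
#'
#' @param path CSV file path.
#' @param run_id Run identifier attached to the returned trace.
#' @return \code{read_trace()} returns a \code{sensor_trace} data.frame.
#' @export
read_trace <- function(path, run_id = NULL) {
  df <- read_checked_csv(path, c("time_s", CHANNELS))
  new_sensor_trace(df, run_id %||% basename_noext(path))
}

#' @rdname read_trace
#' @param trace A \code{sensor_trace}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  out <- data.frame(time_s = fmt_num(trace$time_s),
                    tgs822 = fmt_num(trace$tgs822),
                    tgs813 = fmt_num(trace$tgs813),
                    mq3 = fmt_num(trace$mq3))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write offline pH/TTA series
#'
#' CSV with header \code{time_h,ph,tta}. Validation: strictly increasing time,
#' pH in (0, 14), TTA >= 0; parse errors name the offending row.
#'
#' @param path CSV file path.
#' @param run_id Run identifier.
#' @return \code{read_offline()} returns an \code{offline_series} data.frame.
#' @export
read_offline <- function(path, run_id = NULL) {
  df <- read_checked_csv(path, c("time_h", "ph", "tta"))
  new_offline_series(df, run_id %||% basename_noext(path))
}

#' @rdname read_offline
#' @param offline An \code{offline_series}.
#' @export
write_offline <- function(offline, path) {
  stopifnot(inherits(offline, "offline_series"))
  out <- data.frame(time_h = fmt_num(offline$time_h),
                    ph = fmt_num(offline$ph), tta = fmt_num(offline$tta))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

feature_cols <- function() {
  c("interval", "t_mid_s",
    as.vector(t(outer(c("ph", "pa", "bl"), CHANNELS, paste, sep = "_"))))
}

#' Read and write feature tables
#'
#' CSV with one row per retained 5-minute interval and columns
#' \code{interval,t_mid_s,ph_tgs822,pa_tgs822,bl_tgs822,...}: per channel the
#' raw peak height (PH), trapezoidal peak area (PA, signal*s) and baseline
#' (BL).
#'
#' @param path CSV file path.
#' @param run_id Run identifier.
#' @param cadence Measurement cycle length in seconds.
#' @return \code{read_features()} returns a \code{feature_table} data.frame.
#' @export
read_features <- function(path, run_id = NULL, cadence = 300) {
  cols <- c("interval", "t_mid_s",
            paste(rep(c("ph", "pa", "bl"), 3),
                  rep(CHANNELS, each = 3), sep = "_"))
  df <- read_checked_csv(path, cols)
  df$interval <- as.integer(df$interval)
  new_feature_table(df, run_id %||% basename_noext(path), cadence)
}

#' @rdname read_features
#' @param features A \code{feature_table}.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_table"))
  cols <- c("interval", "t_mid_s",
            paste(rep(c("ph", "pa", "bl"), 3),
                  rep(CHANNELS, each = 3), sep = "_"))
  out <- as.data.frame(lapply(features[cols], fmt_num))
  names(out) <- cols
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_feature_table <- function(df, run_id, cadence) {
  if (any(diff(df$interval) <= 0)) stop("interval indices must be strictly increasing")
  structure(df, run_id = run_id, cadence = cadence,
            class = c("feature_table", "data.frame"))
}

MODEL_FILE_VERSION <- "1"

#' Save and load calibration models
#'
#' Models are stored as version-tagged JSON carrying the method tag
#' (\code{"signal"}, \code{"pca"} or \code{"interval"}), the target
#' (\code{"ph"}/\code{"tta"}), the regression coefficients, and — for the
#' PCA-based methods — the center/scale vectors and loadings without which the
#' coefficients are meaningless. A loaded model predicts identically to the
#' saved one.
#'
#' @param model A fitted calibration model.
#' @param path JSON file path.
#' @return \code{load_model()} returns the model; \code{save_model()} the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ferm_model")) stop("not a fitted calibration model")
  payload <- unclass(model)
  payload$.method <- model_method_tag(model)
  payload$.version <- MODEL_FILE_VERSION
  payload$.package <- paste0("fermsense ",
                             as.character(utils::packageVersion("fermsense")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

model_method_tag <- function(model) {
  if (inherits(model, "gsa_signal_model")) "signal"
  else if (inherits(model, "gsa_pca_model")) "pca"
  else if (inherits(model, "gsa_interval_model")) "interval"
  else stop("unknown model class")
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  method <- payload$.method
  if (is.null(method) || !method %in% c("signal", "pca", "interval")) {
    stop(sprintf("%s: unknown or missing method tag", path))
  }
  required <- switch(method,
    signal = c("target", "feature_kind", "coefficients"),
    pca = c("target", "center", "scale", "loadings", "coefficients"),
    interval = c("target", "L", "center", "loading", "coefficients"))
  missing <- setdiff(required, names(payload))
  if (length(missing)) {
    stop(sprintf("%s: model file missing field(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  payload$.method <- NULL
  payload$.version <- NULL
  payload$.package <- NULL
  if (method == "pca") {
    ld <- payload$loadings
    if (!is.matrix(ld)) ld <- do.call(rbind, lapply(ld, unlist))
    payload$loadings <- matrix(as.numeric(ld), nrow = nrow(ld))
  }
  for (nm in c("center", "scale", "loading")) {
    if (!is.null(payload[[nm]])) payload[[nm]] <- as.numeric(unlist(payload[[nm]]))
  }
  if (!is.null(payload$coefficients)) {
    payload$coefficients <- unlist(payload$coefficients)
  }
  cls <- switch(method, signal = "gsa_signal_model", pca = "gsa_pca_model",
                interval = "gsa_interval_model")
  structure(payload, class = c(cls, "ferm_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))
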