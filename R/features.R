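# Segmentation of raw traces into clock-driven 5-minute measurement cycles
# and extraction of the per-cycle features: peak height (PH), trapezoidal
# peak area (PA) and pre-injection baseline (BL) per channel.

#' Segment a raw trace into measurement cycles
#'
#' The instrument cycle is clock-driven: sample \eqn{j} belongs to cycle
#' \eqn{k = \lfloor t_j / cadence \rfloor}. Segmentation therefore uses fixed
#' clock boundaries, not peak detection; indices preserve the absolute clock,
#' so acquisition gaps leave holes in the index sequence. Segments retaining
#' fewer than \code{min_samples} samples are dropped and reported.
#'
#' @param trace A \code{sensor_trace}.
#' @param cadence Cycle length in seconds (default 300 = 5 minutes).
#' @param tolerance Coverage tolerance in seconds, absorbing sampling jitter:
#'   a segment whose samples span less than \code{cadence - tolerance} is
#'   dropped as incomplete. Defaults to a tenth of the cadence.
#' @param min_samples Minimum samples per retained segment.
#' @return A list of \code{interval_segment} objects, each with fields
#'   \code{index}, \code{t_start}, \code{t_end}, \code{time_s} and a
#'   samples-by-3 \code{channels} matrix.
#' @export
segment_intervals <- function(trace, cadence = 300, tolerance = cadence / 10,
                              min_samples = 20) {
  stopifnot(inherits(trace, "sensor_trace"), cadence > 0)
  if (max(trace$time_s) - min(trace$time_s) < cadence - tolerance) {
    warning("trace shorter than one cadence; no segments")
    return(list())
  }
  idx <- floor(trace$time_s / cadence)
  parts <- split(seq_len(nrow(trace)), idx)
  dropped <- integer(0)
  segs <- list()
  for (nm in names(parts)) {
    rows <- parts[[nm]]
    k <- as.integer(nm)
    span <- trace$time_s[rows[length(rows)]] - trace$time_s[rows[1]]
    if (length(rows) < min_samples || span < cadence - tolerance) {
      dropped <- c(dropped, k)
      next
    }
    segs[[length(segs) + 1]] <- structure(
      list(index = k, t_start = k * cadence, t_end = (k + 1) * cadence,
           time_s = trace$time_s[rows],
           channels = as.matrix(trace[rows, CHANNELS])),
      class = "interval_segment")
  }
  if (length(dropped)) {
    message(sprintf("dropped %d incomplete segment(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  }
  segs
}

#' Baseline of a measurement cycle
#'
#' The baseline BL of each channel is the median of the first \code{n_pre}
#' samples of the segment — signal recorded before the pump starts, so no
#' sample gas is present. The median makes the estimate robust to isolated
#' spikes.
#'
#' @param segment An \code{interval_segment}.
#' @param n_pre Number of pre-injection samples (>= 3).
#' @return Named numeric vector of per-channel baselines.
#' @export
estimate_baseline <- function(segment, n_pre = 5) {
  stopifnot(inherits(segment, "interval_segment"))
  if (n_pre < 3) stop("n_pre must be >= 3")
  if (nrow(segment$channels) < n_pre) {
    stop(sprintf("segment %d has fewer than n_pre = %d samples",
                 segment$index, n_pre))
  }
  apply(segment$channels[seq_len(n_pre), , drop = FALSE], 2, stats::median)
}

#' Extract peak features from one cycle
#'
#' Peak height PH is the raw per-channel maximum over the segment; peak area
#' PA is the trapezoidal integral of the raw signal over the segment's sample
#' times (signal units * s). Both are stored raw — the baseline correction of
#' the calibration equations is applied at regression time, and any constant
#' convention shift is absorbed by the regression intercept.
#'
#' @param segment An \code{interval_segment}.
#' @param baseline Per-channel baseline from [estimate_baseline()].
#' @return One-row data.frame (a \code{FeatureRow}): \code{interval},
#'   \code{t_mid_s}, then \code{ph_*}, \code{pa_*}, \code{bl_*} per channel.
#' @export
extract_features <- function(segment, baseline) {
  stopifnot(inherits(segment, "interval_segment"), length(baseline) == 3)
  ph <- apply(segment$channels, 2, max)
  pa <- apply(segment$channels, 2, function(y) pracma::trapz(segment$time_s, y))
  row <- data.frame(interval = segment$index,
                    t_mid_s = (segment$t_start + segment$t_end) / 2)
  for (i in seq_along(CHANNELS)) {
    row[[paste0("ph_", CHANNELS[i])]] <- ph[i]
    row[[paste0("pa_", CHANNELS[i])]] <- pa[i]
    row[[paste0("bl_", CHANNELS[i])]] <- baseline[i]
  }
  row
}

#' Build the feature table of a run
#'
#' Composition of [segment_intervals()], [estimate_baseline()] and
#' [extract_features()]: one row per retained 5-minute cycle with the six
#' independent variables (PH and PA for each of the three channels) plus the
#' per-channel baselines. Deterministic.
#'
#' @param x A \code{sensor_trace} or a \code{ferm_run}.
#' @param cadence Cycle length (s).
#' @param tolerance Coverage tolerance passed to [segment_intervals()].
#' @param n_pre Pre-injection samples for the baseline.
#' @param min_samples Minimum samples per retained segment.
#' @return A \code{feature_table} data.frame.
#' @export
build_feature_table <- function(x, cadence = 300, tolerance = cadence / 10,
                                n_pre = 5, min_samples = 20) {
  trace <- if (inherits(x, "ferm_run")) x$trace else x
  stopifnot(inherits(trace, "sensor_trace"))
  segs <- segment_intervals(trace, cadence, tolerance, min_samples)
  if (!length(segs)) stop("no retained segments in trace")
  rows <- lapply(segs, function(s) extract_features(s, estimate_baseline(s, n_pre)))
  df <- do.call(rbind, rows)
  new_feature_table(df, attr(trace, "run_id") %||% "run1", cadence)
}
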