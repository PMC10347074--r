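#' Detect calibration flexion bursts
#'
#' The session protocol brackets the recording with a "calibration
#' movement": 3-5 fast arm flexions in camera view. These produce
#' supra-gravity transients in the acceleration norm. Detection: high-pass
#' filter the norm (removing gravity), find samples exceeding the
#' threshold, merge them into bursts, and cluster bursts separated by less
#' than `cluster_gap_s` into calibration events; events with at least
#' `min_bursts` bursts qualify.
#'
#' @param signal An anatomical-convention [accel_signal()].
#' @param threshold_g Burst amplitude threshold on the high-passed norm, g
#'   (must exceed 1; default 1.5 g since a fast flexion exceeds gravity).
#' @param min_bursts Minimum bursts per calibration event (default 3).
#' @param highpass_hz High-pass cutoff removing the gravity component, Hz.
#' @param cluster_gap_s Maximum gap between bursts of one event, seconds.
#' @return Data frame with one row per calibration event: `start_s`,
#'   `end_s`, `n_bursts`.
#' @export
detect_calibration <- function(signal, threshold_g = 1.5, min_bursts = 3,
                               highpass_hz = 0.5, cluster_gap_s = 3) {
  if (threshold_g <= 1)
    stop("threshold_g must exceed 1 g (bursts are supra-gravity transients)")
  fs <- signal$sample_rate_hz
  hp <- highpass_norm(signal, highpass_hz)
  hot <- which(abs(hp) > threshold_g)
  if (length(hot) == 0)
    stop("sync error: no calibration bursts found above ", threshold_g, " g")
  # merge hot samples into bursts (gaps < 0.25 s), then bursts into events
  burst_id <- cumsum(c(1, diff(hot) > 0.25 * fs))
  burst_start <- tapply(hot, burst_id, min)
  burst_end <- tapply(hot, burst_id, max)
  event_id <- cumsum(c(1, diff(burst_start) > cluster_gap_s * fs))
  events <- data.frame(
    start_s = signal$t0 + (tapply(burst_start, event_id, min) - 1) / fs,
    end_s = signal$t0 + tapply(burst_end, event_id, max) / fs,
    n_bursts = as.integer(tapply(burst_start, event_id, length)))
  events <- events[events$n_bursts >= min_bursts, , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) < 2)
    stop("sync error: fewer than 2 calibration events detected; ",
         "session cannot be synchronized")
  events
}

# zero-phase high-passed acceleration norm
highpass_norm <- function(signal, highpass_hz = 0.5) {
  bf <- signal::butter(4, highpass_hz / (signal$sample_rate_hz / 2),
                       type = "high")
  as.numeric(signal::filtfilt(bf, accel_norm(signal)))
}

#' Estimate the inter-sensor clock lag
#'
#' Positive lag means the right stream is delayed relative to the left: the
#' same event appears `lag` seconds later in the right signal. Estimated as
#' the argmax of the normalized cross-correlation of the high-passed
#' acceleration norms over integer-sample lags within `±max_lag_s`,
#' restricted to a window around the calibration events when supplied.
#'
#' @param left,right Anatomical [accel_signal()]s at a common sample rate.
#' @param max_lag_s Search half-width, seconds (default 2).
#' @param window_s Optional `c(start, end)` window (seconds, left/truth
#'   clock) to correlate over, e.g. around a calibration event; `NULL`
#'   correlates the full overlap.
#' @return A list: `lag_s` (seconds, sample resolution), `at_boundary`
#'   (TRUE when the peak sits on the search edge, flagging a lag at or
#'   beyond `max_lag_s`), and `peak_corr`.
#' @export
estimate_lag <- function(left, right, max_lag_s = 2, window_s = NULL) {
  if (left$sample_rate_hz != right$sample_rate_hz)
    stop("signals must share a sample rate")
  fs <- left$sample_rate_hz
  a <- highpass_norm(left)
  b <- highpass_norm(right)
  raw_a <- accel_norm(left)
  raw_b <- accel_norm(right)
  max_lag <- round(max_lag_s * fs)
  if (!is.null(window_s)) {
    # expand both streams identically (indices must stay aligned) with
    # enough slack that the delayed event remains inside the window
    i0 <- max(1, floor((window_s[1] - max_lag_s) * fs) + 1)
    i1 <- min(length(a), length(b),
              ceiling((window_s[2] + max_lag_s) * fs))
    a <- a[i0:i1]; b <- b[i0:i1]
    raw_a <- raw_a[i0:i1]; raw_b <- raw_b[i0:i1]
  }
  n <- min(length(a), length(b))
  a <- a[1:n]; b <- b[1:n]
  # flatness is judged on the unfiltered norm: the zero-phase filter has
  # edge transients even for a constant input
  if (stats::sd(raw_a[1:n]) < 1e-10 || stats::sd(raw_b[1:n]) < 1e-10)
    stop("undefined lag: flat signal in correlation window")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    # correlate a[t] with b[t + k]: right delayed by k samples
    if (k >= 0) {
      ai <- 1:(n - k); bi <- (1 + k):n
    } else {
      ai <- (1 - k):n; bi <- 1:(n + k)
    }
    if (stats::sd(a[ai]) < 1e-10 || stats::sd(b[bi]) < 1e-10) return(-Inf)
    stats::cor(a[ai], b[bi])
  }, numeric(1))
  if (!any(is.finite(cc)))
    stop("undefined lag: flat signal in correlation window")
  best <- which.max(cc)
  list(lag_s = lags[best] / fs,
       at_boundary = best == 1 || best == length(lags),
       peak_corr = cc[best])
}

#' Synchronize a bilateral session
#'
#' Runs calibration detection on the left signal, estimates the
#' right-vs-left clock lag in the first calibration window, and reports the
#' trim boundaries (end of the first calibration event, start of the
#' second). A spot check re-estimates the lag in the second calibration
#' window; the difference is reported as drift but no drift correction is
#' applied.
#'
#' @param left,right Anatomical [accel_signal()]s.
#' @param threshold_g,min_bursts,highpass_hz,cluster_gap_s Passed to
#'   [detect_calibration()].
#' @param max_lag_s Passed to [estimate_lag()].
#' @return A list of class `sync_result`: `first_calibration_end_s`,
#'   `second_calibration_start_s`, `lag_right_vs_left_s`,
#'   `spot_check_drift_s`, `lag_at_boundary`.
#' @export
synchronize_session <- function(left, right, threshold_g = 1.5,
                                min_bursts = 3, highpass_hz = 0.5,
                                cluster_gap_s = 3, max_lag_s = 2) {
  events <- detect_calibration(left, threshold_g, min_bursts, highpass_hz,
                               cluster_gap_s)
  first <- events[1, ]
  second <- events[nrow(events), ]
  lag1 <- estimate_lag(left, right, max_lag_s,
                       window_s = c(first$start_s - 1, first$end_s + 1))
  lag2 <- estimate_lag(left, right, max_lag_s,
                       window_s = c(second$start_s - 1, second$end_s + 1))
  structure(
    list(first_calibration_end_s = first$end_s,
         second_calibration_start_s = second$start_s,
         lag_right_vs_left_s = lag1$lag_s,
         spot_check_drift_s = lag2$lag_s - lag1$lag_s,
         lag_at_boundary = lag1$at_boundary || lag2$at_boundary),
    class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> retain [%.2f, %.2f) s | right lag %+.3f s | drift %+.3f s\n",
    x$first_calibration_end_s, x$second_calibration_start_s,
    x$lag_right_vs_left_s, x$spot_check_drift_s))
  invisible(x)
}

#' Shift a signal's content in time
#'
#' Realigns a stream whose clock lags the reference: `shift_signal(sig,
#' -lag)` drops the first `lag` seconds so that events line up with the
#' reference clock. The time origin `t0` is preserved.
#'
#' @param signal An [accel_signal()].
#' @param by_s Shift in seconds (rounded to whole samples); negative drops
#'   leading samples, positive prepends copies of the first sample.
#' @return The shifted signal (same length is not preserved for negative
#'   shifts; the tail is simply shorter).
#' @export
shift_signal <- function(signal, by_s) {
  k <- round(by_s * signal$sample_rate_hz)
  if (k == 0) return(signal)
  out <- signal
  for (axis in c("x", "y", "z")) {
    v <- signal[[axis]]
    out[[axis]] <- if (k < 0) v[(-k + 1):length(v)]
                   else c(rep(v[1], k), v)
  }
  out
}

#' Trim a signal and its annotation track to the calibration interval
#'
#' Retains the span from the end of the first calibration event to the
#' start of the second; everything recorded before the first and after the
#' second calibration is discarded. Signal and track stay aligned (both are
#' cut at the same wall-clock boundaries; `t0` keeps the wall-clock trim
#' start, so trimming an already-trimmed session is the identity).
#' Calibration frames inside the retained span keep category 0 and fall out
#' later as unknown epochs.
#'
#' @param signal An [accel_signal()] on the reference (left/video) clock.
#' @param track The matching [annotation_track()], or `NULL`.
#' @param sync A `sync_result` from [synchronize_session()].
#' @return List with elements `signal` and `track`.
#' @export
trim_to_calibration <- function(signal, track, sync) {
  a <- sync$first_calibration_end_s
  b <- sync$second_calibration_start_s
  if (b <= a) stop("empty interior: second calibration does not follow first")
  fs <- signal$sample_rate_hz
  i0 <- floor((a - signal$t0) * fs) + 1
  i1 <- floor((b - signal$t0) * fs)
  if (i1 < i0) stop("empty interior after rounding to samples")
  i0 <- max(i0, 1); i1 <- min(i1, n_samples(signal))
  out_sig <- signal
  for (axis in c("x", "y", "z")) out_sig[[axis]] <- signal[[axis]][i0:i1]
  out_sig$t0 <- signal$t0 + (i0 - 1) / fs
  out_trk <- NULL
  if (!is.null(track)) {
    fps <- track$frame_rate_fps
    j0 <- max(floor((a - track$t0) * fps) + 1, 1)
    j1 <- min(floor((b - track$t0) * fps), n_frames(track))
    out_trk <- annotation_track(track$labels[j0:j1], fps,
                                t0 = track$t0 + (j0 - 1) / fps)
  }
  list(signal = out_sig, track = out_trk)
}
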