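# Published band-pass filter coefficients of the ActiGraph counts chain at
# 30 Hz (Brond et al. 2017, as republished with the open-source counts
# specification). Applied as an IIR filter with gain 0.965; the remaining
# chain constants: decimation to 10 Hz, +/-2.13 g clip, 0.068 g deadband,
# 0.0164 g quantisation step.
counts_filter_b <- c(
  0.049109, -0.12284, 0.14356, -0.11269, 0.053804, -0.02023,
  0.0063778, 0.018513, -0.038154, 0.048727, -0.052577, 0.047847,
  -0.046015, 0.036283, -0.012977, -0.0046262, 0.012835, -0.0093762,
  0.0034485, -0.00080972, -0.00019623)
counts_filter_a <- c(
  1, -4.1637, 7.5712, -7.9805, 5.385, -2.4636, 0.89238, 0.06361,
  -1.3481, 2.4734, -2.9257, 2.9298, -2.7816, 2.4777, -1.6847,
  0.46483, 0.46565, -0.67312, 0.4162, -0.13832, 0.019852)
counts_gain <- 0.965
counts_peak_g <- 2.13
counts_deadband_g <- 0.068
counts_adc_g <- 0.0164
counts_warmup_samples <- 900L  # 30 s of first-sample padding settles the IIR

# zero-state IIR with first-sample padding so a constant input sits in the
# filter's (zero-DC) steady state before the data start
counts_bpf <- function(x) {
  b <- counts_filter_b * counts_gain
  a <- counts_filter_a
  pad <- rep(x[1], counts_warmup_samples)
  y <- signal::filter(signal::Arma(b = b, a = a), c(pad, x))
  as.numeric(y)[(counts_warmup_samples + 1):(counts_warmup_samples + length(x))]
}

#' Convert raw acceleration to per-epoch activity counts
#'
#' Implements the published open-source activity-counts chain for 30 Hz
#' input, per axis: band-pass filter (IIR, coefficients above), decimation
#' from 30 Hz to 10 Hz (every third sample), clipping at ±2.13 g,
#' rectification, a 0.068 g deadband, quantisation to 0.0164 g resolution
#' (floor), and summation over the epoch. The filter has zero DC gain, so a
#' constant (gravity-only) signal yields zero counts on every axis.
#'
#' @param signal An [accel_signal()] sampled at 30 Hz.
#' @param epoch_len_s Counts epoch length in seconds (default 1, the epoch
#'   size of the baseline method).
#' @return An object of class `counts_series`: list with `epoch_len_s`,
#'   integer vectors `counts_x`, `counts_y`, `counts_z`, and `magnitude`
#'   (per-epoch Euclidean norm of the three axis counts).
#' @export
accel_to_counts <- function(signal, epoch_len_s = 1) {
  if (signal$sample_rate_hz != 30)
    stop("counts conversion requires 30 Hz input (got ",
         signal$sample_rate_hz, " Hz)")
  per_axis <- function(x) {
    y <- counts_bpf(x)
    ds <- y[seq(1, length(y), by = 3)]           # 30 Hz -> 10 Hz
    ds <- pmax(pmin(ds, counts_peak_g), -counts_peak_g)
    ds <- abs(ds)
    ds[ds < counts_deadband_g] <- 0
    q <- floor(ds / counts_adc_g)
    spe <- 10 * epoch_len_s                      # samples per epoch at 10 Hz
    n_epochs <- length(q) %/% spe
    as.integer(colSums(matrix(q[seq_len(n_epochs * spe)], nrow = spe)))
  }
  cx <- per_axis(signal$x)
  cy <- per_axis(signal$y)
  cz <- per_axis(signal$z)
  structure(list(epoch_len_s = epoch_len_s,
                 counts_x = cx, counts_y = cy, counts_z = cz,
                 magnitude = sqrt(cx^2 + cy^2 + cz^2)),
            class = "counts_series")
}

#' @export
print.counts_series <- function(x, ...) {
  cat(sprintf("<counts_series> %d epochs of %g s; magnitude range [%g, %g]\n",
              length(x$magnitude), x$epoch_len_s,
              min(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Active minutes by the counts-threshold baseline
#'
#' A 1-s epoch is "active" when the vector magnitude of its axis counts
#' exceeds the threshold (default 1 count). Total active minutes is the
#' number of active epochs times the epoch length over 60. The magnitude
#' convention is the standard vector-magnitude rule; `per_axis_or = TRUE`
#' switches to flagging an epoch active when any single axis exceeds the
#' threshold.
#'
#' @param series A `counts_series`.
#' @param threshold Counts threshold (epoch active iff counts > threshold).
#' @param per_axis_or Use per-axis OR logic instead of the vector magnitude.
#' @return List with `minutes` and logical `active` flags per epoch.
#' @export
active_minutes_counts <- function(series, threshold = 1, per_axis_or = FALSE) {
  stopifnot(inherits(series, "counts_series"))
  active <- if (per_axis_or) {
    series$counts_x > threshold | series$counts_y > threshold |
      series$counts_z > threshold
  } else {
    series$magnitude > threshold
  }
  list(minutes = sum(active) * series$epoch_len_s / 60, active = active)
}

#' Fraction of the session active by the counts baseline
#'
#' @param series A `counts_series`.
#' @param total_time_s Duration of the trimmed session, seconds.
#' @param threshold,per_axis_or As in [active_minutes_counts()].
#' @return Active time divided by total time, in `[0, 1]`.
#' @export
percent_active_counts <- function(series, total_time_s, threshold = 1,
                                  per_axis_or = FALSE) {
  if (total_time_s <= 0) stop("total_time_s must be positive")
  am <- active_minutes_counts(series, threshold, per_axis_or)
  min(am$minutes * 60 / total_time_s, 1)
}
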