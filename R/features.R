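# frozen feature order: serialization contract with the classifier
feature_names <- c("mean_x", "mean_y", "mean_z",
                   "var_x", "var_y", "var_z",
                   "norm_mean", "norm_var", "norm_min", "norm_max",
                   "norm_entropy")

#' Resample a 30 Hz signal to 50 Hz by cubic spline interpolation
#'
#' Each axis is interpolated with a cubic spline and re-evaluated on a
#' 50 Hz grid, matching the sampling rate the epoch classifier was built
#' for. The output length is `round(n * 50/30)`, preserving the duration
#' within one output sample.
#'
#' @param signal An [accel_signal()] at 30 Hz (a 50 Hz input passes through
#'   unchanged with a message).
#' @param target_hz Target rate, default 50.
#' @return The resampled `accel_signal`.
#' @export
resample_to_50hz <- function(signal, target_hz = 50) {
  if (signal$sample_rate_hz == target_hz) {
    message("signal already at ", target_hz, " Hz; returning unchanged")
    return(signal)
  }
  fs <- signal$sample_rate_hz
  n_in <- n_samples(signal)
  if (n_in < 4) stop("too few samples to spline-resample")
  t_in <- (seq_len(n_in) - 1) / fs
  n_out <- round(n_in * target_hz / fs)
  t_out <- (seq_len(n_out) - 1) / target_hz
  out <- signal
  for (axis in c("x", "y", "z"))
    out[[axis]] <- stats::spline(t_in, signal[[axis]], xout = t_out,
                                 method = "fmm")$y
  out$sample_rate_hz <- target_hz
  out
}

#' Shannon entropy of a sample by epoch-relative histogram
#'
#' Probabilities are bin occupancy fractions over `n_bins` equal-width bins
#' spanning the sample's own range; `0 * log2(0)` is taken as 0. A constant
#' sample (zero range) has entropy 0. The estimate is invariant under
#' adding a constant because the bin edges travel with the data.
#'
#' @param v Numeric vector.
#' @param n_bins Number of histogram bins, default 16.
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(v, n_bins = 16) {
  r <- range(v)
  if (r[1] == r[2]) return(0)
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-epoch feature vectors from a 50 Hz signal
#'
#' Computes the 11 features of the epoch classifier for each non-overlapping
#' 4-s epoch (200 samples at 50 Hz), anchored at the signal start: mean and
#' variance of each axis, plus mean, variance, minimum, maximum and Shannon
#' entropy of the per-sample Euclidean norm. Variances are population
#' variances (divide by n). A trailing epoch with fewer than the full
#' sample count is dropped.
#'
#' @param signal An anatomical [accel_signal()] at 50 Hz.
#' @param epoch_len_s Epoch length, seconds (default 4).
#' @param entropy_bins Histogram bins for the entropy estimator (default 16).
#' @return Numeric matrix, one row per epoch, 11 named columns in the
#'   frozen feature order.
#' @export
epoch_features <- function(signal, epoch_len_s = 4, entropy_bins = 16) {
  spe <- signal$sample_rate_hz * epoch_len_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("sample_rate_hz * epoch_len_s must be integral")
  spe <- as.integer(round(spe))
  n_epochs <- n_samples(signal) %/% spe
  if (n_epochs < 1) stop("signal shorter than one epoch")
  pop_var <- function(v) mean((v - mean(v))^2)
  nrm <- accel_norm(signal)
  out <- matrix(NA_real_, n_epochs, length(feature_names),
                dimnames = list(NULL, feature_names))
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1) * spe + 1):(e * spe)
    nv <- nrm[idx]
    out[e, ] <- c(mean(signal$x[idx]), mean(signal$y[idx]), mean(signal$z[idx]),
                  pop_var(signal$x[idx]), pop_var(signal$y[idx]),
                  pop_var(signal$z[idx]),
                  mean(nv), pop_var(nv), min(nv), max(nv),
                  shannon_entropy(nv, entropy_bins))
  }
  out
}

#' Fit a min-max scaler on a training feature matrix
#'
#' @param features Numeric matrix with the 11 named feature columns.
#' @return An object of class `minmax_scaler` holding per-column minima and
#'   maxima and the feature-order signature.
#' @export
fit_minmax <- function(features) {
  if (is.null(dim(features)) || nrow(features) == 0)
    stop("empty feature set")
  structure(list(min = apply(features, 2, min),
                 max = apply(features, 2, max),
                 signature = colnames(features)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each column by `(v - min) / (max - min)` using the fitted range and
#' clips to `[0, 1]`, so later data outside the training range cannot leave
#' the unit interval. A column that was constant during fitting maps to 0.
#'
#' @param scaler A `minmax_scaler`.
#' @param features Feature matrix with the same column signature.
#' @return Scaled feature matrix.
#' @export
apply_minmax <- function(scaler, features) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (!identical(colnames(features), scaler$signature))
    stop("feature column signature does not match the fitted scaler")
  out <- features
  for (j in seq_len(ncol(features))) {
    rng <- scaler$max[j] - scaler$min[j]
    out[, j] <- if (rng == 0) 0
                else pmin(pmax((features[, j] - scaler$min[j]) / rng, 0), 1)
  }
  out
}

#' Write a feature matrix to CSV
#' @param features Feature matrix from [epoch_features()].
#' @param path Output path.
#' @param side Optional side tag column.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, side = NA_character_) {
  df <- data.frame(epoch = seq_len(nrow(features)), side = side, features)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
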