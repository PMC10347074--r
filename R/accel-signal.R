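#' Tri-axial wrist acceleration signal
#'
#' Container for a raw tri-axial acceleration stream from one wrist-worn
#' sensor. Axes are either in the sensor's `"native"` orientation (as read
#' from the device CSV) or in the `"anatomical"` convention used throughout
#' the analysis chain: x vertical along the forearm (cranial positive),
#' y medio-lateral (medial positive on the right hand, lateral positive on
#' the left hand), z anterior-posterior (anterior positive). All values are
#' in g; time is in seconds.
#'
#' @param x,y,z Numeric vectors of equal length, acceleration in g.
#' @param sample_rate_hz Sampling rate in Hz (30 native, 50 after resampling).
#' @param side `"left"` or `"right"`.
#' @param convention `"native"` or `"anatomical"`.
#' @param t0 Wall-clock start time of the first sample, seconds.
#' @return An object of class `accel_signal`.
#' @export
accel_signal <- function(x, y, z, sample_rate_hz, side,
                         convention = c("native", "anatomical"), t0 = 0) {
  convention <- match.arg(convention)
  side <- match.arg(side, c("left", "right"))
  if (length(x) != length(y) || length(x) != length(z))
    stop("x, y, z must have equal length")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         sample_rate_hz = sample_rate_hz, side = side,
         convention = convention, t0 = t0),
    class = "accel_signal")
}

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf("<accel_signal> %s wrist, %s axes, %d samples @ %g Hz (%.1f s)\n",
              x$side, x$convention, length(x$x), x$sample_rate_hz,
              n_samples(x) / x$sample_rate_hz))
  invisible(x)
}

#' Number of samples in a signal
#' @param signal An `accel_signal`.
#' @return Integer sample count.
#' @export
n_samples <- function(signal) length(signal$x)

#' Signal duration in seconds
#' @param signal An `accel_signal`.
#' @return Duration `n / fs` in seconds.
#' @export
signal_duration <- function(signal) n_samples(signal) / signal$sample_rate_hz

#' Per-sample Euclidean norm of acceleration
#' @param signal An `accel_signal`.
#' @return Numeric vector `sqrt(x^2 + y^2 + z^2)` in g.
#' @export
accel_norm <- function(signal) sqrt(signal$x^2 + signal$y^2 + signal$z^2)

#' Read a raw acceleration CSV
#'
#' The interchange format is a plain CSV with header `time,x,y,z`: time in
#' seconds, acceleration in g at a constant sampling rate. The sampling rate
#' is inferred from the median time step; extraction from native device
#' containers is out of scope and delegated to upstream tooling.
#'
#' @param path Path to the CSV file.
#' @param side `"left"` or `"right"`.
#' @return An `accel_signal` with `convention = "native"`.
#' @export
read_accel_csv <- function(path, side) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-numeric or missing value in column '", col, "' at row ", bad[1],
           " of ", path)
  }
  if (nrow(df) < 2) stop("need at least 2 samples to infer sample rate: ", path)
  dt <- stats::median(diff(df$time))
  accel_signal(df$x, df$y, df$z, sample_rate_hz = round(1 / dt, 6),
               side = side, convention = "native", t0 = df$time[1])
}

#' Write a raw acceleration CSV
#' @param signal An `accel_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(signal, path) {
  t <- signal$t0 + (seq_len(n_samples(signal)) - 1) / signal$sample_rate_hz
  df <- data.frame(time = t, x = signal$x, y = signal$y, z = signal$z)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default native-to-anatomical mounting map
#'
#' A mounting map is a signed permutation taking the sensor's native axes to
#' the anatomical convention. Each entry names a native axis with an optional
#' sign, in anatomical (x, y, z) order. The default describes a wrist-worn
#' sensor with its native y axis along the forearm pointing distally and its
#' native x axis across the wrist; left and right differ only in the sign of
#' the medio-lateral axis, mirroring the two hands. The mapping is
#' configurable because device mounting conventions vary.
#'
#' @param side `"left"` or `"right"`.
#' @return Character vector of length 3, e.g. `c("-y", "-x", "z")`.
#' @export
default_mounting <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") c("-y", "-x", "z") else c("-y", "x", "z")
}

# parse a mounting map into a signed 3x3 permutation matrix (rows = anatomical)
mounting_matrix <- function(map) {
  if (length(map) != 3) stop("mounting map must have 3 entries")
  m <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (i in 1:3) {
    entry <- map[i]
    sign <- if (startsWith(entry, "-")) -1 else 1
    axis <- sub("^[-+]", "", entry)
    if (!axis %in% c("x", "y", "z"))
      stop("unknown axis in mounting map: '", entry, "'")
    m[i, axis] <- sign
  }
  if (any(colSums(abs(m)) != 1))
    stop("mounting map must be a signed permutation (each native axis used once)")
  m
}

#' Remap a native signal into the anatomical axis convention
#'
#' Applies the signed-permutation mounting map, so the per-sample Euclidean
#' norm is preserved exactly. Left and right wrists use mirrored
#' medio-lateral signs (medial positive on the right, lateral positive on
#' the left).
#'
#' @param signal An `accel_signal` with `convention = "native"`.
#' @param map Mounting map as in [default_mounting()]; defaults to the map
#'   for `signal$side`.
#' @return The signal with `convention = "anatomical"`.
#' @export
to_anatomical <- function(signal, map = default_mounting(signal$side)) {
  if (signal$convention == "anatomical") {
    message("signal already in anatomical convention; returning unchanged")
    return(signal)
  }
  m <- mounting_matrix(map)
  native <- rbind(signal$x, signal$y, signal$z)
  anat <- m %*% native
  out <- signal
  out$x <- as.numeric(anat[1, ])
  out$y <- as.numeric(anat[2, ])
  out$z <- as.numeric(anat[3, ])
  out$convention <- "anatomical"
  out
}

# inverse remap, used by the simulator's CSV writer
from_anatomical <- function(signal, map = default_mounting(signal$side)) {
  m <- mounting_matrix(map)
  native <- t(m) %*% rbind(signal$x, signal$y, signal$z)  # inverse of a signed permutation
  out <- signal
  out$x <- as.numeric(native[1, ])
  out$y <- as.numeric(native[2, ])
  out$z <- as.numeric(native[3, ])
  out$convention <- "native"
  out
}
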