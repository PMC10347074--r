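#' Frame-level annotation track
#'
#' Per-video-frame categorical labels for one arm side, following the
#' three-category video-annotation scheme: 0 = unknown (includes the
#' calibration procedure), 1 = non-functional movement (arm swing during
#' walking, quiet sitting), 2 = functional, task-specific movement.
#'
#' @param labels Integer vector of frame labels in \{0, 1, 2\}.
#' @param frame_rate_fps Frame rate in Hz (25 for the reference camera).
#' @param t0 Wall-clock time of the first frame, seconds.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(labels, frame_rate_fps = 25, t0 = 0) {
  labels <- as.integer(labels)
  if (any(!labels %in% 0:2)) stop("labels must be in {0, 1, 2}")
  if (frame_rate_fps <= 0) stop("frame_rate_fps must be positive")
  structure(list(labels = labels, frame_rate_fps = frame_rate_fps, t0 = t0),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf(
    "<annotation_track> %d frames @ %g fps (%.1f s) | unknown %d, non-functional %d, functional %d\n",
    length(x$labels), x$frame_rate_fps, length(x$labels) / x$frame_rate_fps,
    tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

#' Number of frames in a track
#' @param track An `annotation_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) length(track$labels)

#' Read an annotation-marker CSV
#'
#' Markers are exported from the annotated video timeline as spans with
#' columns `start_s,end_s,side,category`. Frames not covered by any marker
#' default to category 1 (non-functional); markers for categories 0 and 2
#' override that default.
#'
#' @param path Path to the marker CSV.
#' @return A data frame of markers.
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("start_s", "end_s", "side", "category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  if (any(df$end_s <= df$start_s)) stop("marker with end_s <= start_s in ", path)
  if (any(!df$category %in% 0:2)) stop("marker category outside {0,1,2} in ", path)
  df
}

#' Write an annotation-marker CSV
#' @param markers Data frame with columns `start_s,end_s,side,category`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  utils::write.csv(markers[, c("start_s", "end_s", "side", "category")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Rasterise timeline markers into a per-frame track
#'
#' @param markers Marker data frame (see [read_marker_csv()]).
#' @param side `"left"` or `"right"`; only markers for that side are applied.
#' @param duration_s Total span to rasterise, seconds.
#' @param frame_rate_fps Frame rate, default 25.
#' @param t0 Start time of the first frame, seconds.
#' @return An `annotation_track`. Frames outside all markers are category 1.
#' @export
markers_to_track <- function(markers, side, duration_s, frame_rate_fps = 25,
                             t0 = 0) {
  side <- match.arg(side, c("left", "right"))
  n <- floor(duration_s * frame_rate_fps)
  labels <- rep(1L, n)
  t <- t0 + (seq_len(n) - 1) / frame_rate_fps
  ms <- markers[markers$side == side, , drop = FALSE]
  for (i in seq_len(nrow(ms))) {
    sel <- t >= ms$start_s[i] & t < ms$end_s[i]
    labels[sel] <- as.integer(ms$category[i])
  }
  annotation_track(labels, frame_rate_fps, t0)
}

#' Convert a track back to timeline markers
#'
#' Inverse of [markers_to_track()]: runs of category 0 and 2 frames become
#' spans; category-1 frames are the implicit background.
#'
#' @param track An `annotation_track`.
#' @param side Side tag written into the marker rows.
#' @return Marker data frame with columns `start_s,end_s,side,category`.
#' @export
track_to_markers <- function(track, side) {
  r <- rle(track$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 1L
  data.frame(
    start_s = track$t0 + starts[keep] / track$frame_rate_fps,
    end_s = track$t0 + ends[keep] / track$frame_rate_fps,
    side = side,
    category = r$values[keep])
}
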