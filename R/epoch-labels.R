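#' Collapse frame-level annotations into 4-s epoch labels
#'
#' Epochs tile the track from its first frame, non-overlapping; a trailing
#' partial epoch is dropped. An epoch takes the label of the category
#' holding a strict majority (more than 50 percent) of its frames
#' (`functional`, `non_functional` or `unknown`); with no strict majority
#' the epoch is `mixed`.
#'
#' @param track An [annotation_track()] (already trimmed to the analysed
#'   span).
#' @param epoch_len_s Epoch length in seconds, default 4. The frame count
#'   per epoch (`frame_rate_fps * epoch_len_s`) must be integral.
#' @return An object of class `epoch_labels`: a list with `epoch_len_s`,
#'   `labels` (character vector over epochs) and `n_frames_per_epoch`.
#' @export
frames_to_epochs <- function(track, epoch_len_s = 4) {
  stopifnot(inherits(track, "annotation_track"))
  fpe <- track$frame_rate_fps * epoch_len_s
  if (abs(fpe - round(fpe)) > 1e-9)
    stop("frame_rate_fps * epoch_len_s must be an integer frame count")
  fpe <- as.integer(round(fpe))
  n_epochs <- length(track$labels) %/% fpe
  if (n_epochs < 1) stop("track shorter than one epoch")
  m <- matrix(track$labels[seq_len(n_epochs * fpe)], nrow = fpe)
  name_of <- c("unknown", "non_functional", "functional")
  labels <- apply(m, 2, function(fr) {
    counts <- tabulate(fr + 1L, nbins = 3L)
    top <- which.max(counts)
    if (counts[top] > fpe / 2) name_of[top] else "mixed"
  })
  structure(list(epoch_len_s = epoch_len_s, labels = labels,
                 n_frames_per_epoch = fpe),
            class = "epoch_labels")
}

#' @export
print.epoch_labels <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("functional", "non_functional", "mixed", "unknown")))
  cat(sprintf("<epoch_labels> %d epochs of %g s: %s\n",
              length(x$labels), x$epoch_len_s,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Binary ground truth from epoch labels
#'
#' Relabels epochs to the binary scheme used for training and scoring:
#' functional = 1, non-functional = 0. Unknown epochs are always discarded;
#' mixed epochs are handled by `mixed_policy` (the default discards them,
#' keeping training and evaluation symmetric).
#'
#' @param series An `epoch_labels` object.
#' @param mixed_policy One of `"exclude"`, `"as_functional"`,
#'   `"as_nonfunctional"`.
#' @return A list with `binary` (integer 0/1 vector over retained epochs)
#'   and `retained_index` (strictly increasing positions of the retained
#'   epochs in the original epoch sequence).
#' @export
binary_truth <- function(series,
                         mixed_policy = c("exclude", "as_functional",
                                          "as_nonfunctional")) {
  stopifnot(inherits(series, "epoch_labels"))
  mixed_policy <- match.arg(mixed_policy)
  lab <- series$labels
  value <- rep(NA_integer_, length(lab))
  value[lab == "functional"] <- 1L
  value[lab == "non_functional"] <- 0L
  value[lab == "mixed"] <- switch(mixed_policy,
                                  exclude = NA_integer_,
                                  as_functional = 1L,
                                  as_nonfunctional = 0L)
  keep <- which(!is.na(value))
  list(binary = value[keep], retained_index = keep)
}
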