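#' Confusion matrix of epoch predictions
#'
#' The positive class is functional arm use: TP counts epochs predicted and
#' annotated functional, TN epochs predicted and annotated non-functional.
#'
#' @param pred,truth Equal-length integer 0/1 vectors.
#' @return An object of class `confusion_matrix` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (any(!pred %in% 0:1) || any(!truth %in% 0:1))
    stop("labels must be 0/1")
  structure(list(TP = sum(pred == 1 & truth == 1),
                 FP = sum(pred == 1 & truth == 0),
                 FN = sum(pred == 0 & truth == 1),
                 TN = sum(pred == 0 & truth == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)` and the f1-score (harmonic mean of precision and
#' recall). A metric with a zero denominator is degenerate: it is reported
#' as 0 and flagged in `degenerate`, rather than propagating NaN, which
#' keeps cohort averages well defined while staying auditable.
#'
#' @param cm A [confusion()] result.
#' @return List of class `metrics_report`: `accuracy`, `recall`,
#'   `specificity`, `precision`, `f1`, and a character vector `degenerate`
#'   naming any zero-denominator metrics.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$FP + cm$FN + cm$TN
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  accuracy <- safe(cm$TP + cm$TN, n, "accuracy")
  recall <- safe(cm$TP, cm$TP + cm$FN, "recall")
  precision <- safe(cm$TP, cm$TP + cm$FP, "precision")
  specificity <- safe(cm$TN, cm$TN + cm$FP, "specificity")
  f1 <- safe(2 * recall * precision, recall + precision, "f1")
  structure(list(accuracy = accuracy, recall = recall,
                 specificity = specificity, precision = precision, f1 = f1,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> acc %.3f | recall %.3f | spec %.3f | prec %.3f | f1 %.3f%s\n",
    x$accuracy, x$recall, x$specificity, x$precision, x$f1,
    if (length(x$degenerate))
      paste0(" [degenerate: ", paste(x$degenerate, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Functional-use summary per estimation method
#'
#' Converts per-epoch functional flags from the three estimation routes
#' (video ground truth, epoch classifier, counts baseline) into total
#' functional minutes and the percentage of the trimmed session spent
#' functionally active (functional time / total session time).
#'
#' @param truth_epochs Integer 0/1 ground-truth labels over retained 4-s
#'   epochs.
#' @param mlm_epochs Integer 0/1 classifier predictions over all 4-s epochs.
#' @param counts_active Logical per-1-s-epoch activity flags from
#'   [active_minutes_counts()].
#' @param session_duration_s Duration of the trimmed session, seconds.
#' @param epoch_len_s Length of the classification epochs, default 4 s.
#' @return Data frame with one row per method (`ground_truth`, `mlm`,
#'   `counts`) and columns `minutes`, `percent` (fraction in `[0, 1]`).
#' @export
use_summary <- function(truth_epochs, mlm_epochs, counts_active,
                        session_duration_s, epoch_len_s = 4) {
  if (session_duration_s <= 0) stop("session_duration_s must be positive")
  mins <- c(ground_truth = sum(truth_epochs == 1L) * epoch_len_s / 60,
            mlm = sum(mlm_epochs == 1L) * epoch_len_s / 60,
            counts = sum(counts_active) / 60)
  data.frame(method = names(mins),
             minutes = as.numeric(mins),
             percent = pmin(as.numeric(mins) * 60 / session_duration_s, 1),
             row.names = NULL)
}

#' Cohort mean difference from ground truth
#'
#' Mean and SD over participants of (method percentage - ground-truth
#' percentage) of functionally active time, the cohort summary used to
#' quantify how much each estimation method overestimates arm use.
#'
#' @param cohort_use Long data frame with columns `subj_id`, `side`,
#'   `method`, `percent` (as returned by [cohort_use_table()]).
#' @param method `"mlm"` or `"counts"` (or `"ground_truth"`, giving 0).
#' @param side `"left"` or `"right"`.
#' @return List with `mean` and `sd` of the per-participant differences.
#' @export
mean_difference <- function(cohort_use, method, side) {
  sel <- function(m) {
    d <- cohort_use[cohort_use$method == m & cohort_use$side == side, ]
    d <- d[order(d$subj_id), ]
    stats::setNames(d$percent, d$subj_id)
  }
  gt <- sel("ground_truth")
  mt <- sel(method)
  if (length(gt) < 2) stop("need at least 2 participants")
  if (!identical(names(gt), names(mt)))
    stop("missing participant values for method '", method, "': ",
         paste(setdiff(names(gt), names(mt)), collapse = ", "))
  d <- mt - gt
  list(mean = mean(d), sd = stats::sd(d))
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, the standard tie-corrected Spearman
#' statistic, with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_tied <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
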