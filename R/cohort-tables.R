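cohort_file <- function(name) {
  path <- system.file("extdata", name, package = "armuse")
  if (path == "") path <- file.path("inst", "extdata", name)  # pre-install
  if (!file.exists(path)) stop("packaged table not found: ", name)
  path
}

#' Packaged validation-cohort tables
#'
#' The published per-participant values of the ten-participant home
#' validation cohort ship with the package as plain CSV fixtures:
#' demographics with QuickDASH scores, per-side classifier metrics against
#' the video ground truth, and per-side functional-use summaries (minutes
#' and fraction functionally active) for all three estimation methods.
#' The underlying recordings are not publicly available; these printed
#' summary values are the in-package basis for recomputing the cohort
#' statistics.
#'
#' @return A data frame (`cohort_demographics_table`: one row per
#'   participant; `cohort_metrics_table`: one row per participant x side;
#'   `cohort_use_table`: one row per participant x side x method).
#' @export
cohort_demographics_table <- function() {
  utils::read.csv(cohort_file("cohort_demographics.csv"), comment.char = "#")
}

#' @rdname cohort_demographics_table
#' @export
cohort_metrics_table <- function() {
  utils::read.csv(cohort_file("cohort_metrics.csv"), comment.char = "#")
}

#' @rdname cohort_demographics_table
#' @export
cohort_use_table <- function() {
  utils::read.csv(cohort_file("cohort_use.csv"), comment.char = "#")
}

#' Column averages of the cohort metrics table
#'
#' Recomputes the cohort-average row (accuracy, recall, specificity,
#' f1-score per side) from the per-participant values.
#'
#' @param metrics_table Data frame from [cohort_metrics_table()].
#' @return Data frame with one row per side and averaged metric columns.
#' @export
cohort_metric_averages <- function(metrics_table = cohort_metrics_table()) {
  out <- aggregate(metrics_table[, c("accuracy", "recall", "specificity", "f1")],
                   by = list(side = metrics_table$side), FUN = mean)
  out[order(out$side), ]
}

#' Cohort mean differences from ground truth, both methods and sides
#'
#' @param use_table Data frame from [cohort_use_table()].
#' @return Data frame with columns `method`, `side`, `mean`, `sd`.
#' @export
cohort_mean_differences <- function(use_table = cohort_use_table()) {
  grid <- expand.grid(method = c("mlm", "counts"),
                      side = c("left", "right"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    md <- mean_difference(use_table, grid$method[i], grid$side[i])
    data.frame(method = grid$method[i], side = grid$side[i],
               mean = md$mean, sd = md$sd)
  })
  do.call(rbind, res)
}

#' Spearman correlation of disability score with classifier accuracy
#'
#' Tie-corrected Spearman correlation between the cohort QuickDASH scores
#' and the per-participant classifier accuracy, per side.
#'
#' @param demographics Data frame from [cohort_demographics_table()].
#' @param metrics_table Data frame from [cohort_metrics_table()].
#' @return Data frame with columns `side`, `rho`, `p_value`, `n`.
#' @export
cohort_accuracy_correlation <- function(
    demographics = cohort_demographics_table(),
    metrics_table = cohort_metrics_table()) {
  demographics <- demographics[order(demographics$subj_id), ]
  res <- lapply(c("left", "right"), function(s) {
    m <- metrics_table[metrics_table$side == s, ]
    m <- m[order(m$subj_id), ]
    if (!identical(m$subj_id, demographics$subj_id))
      stop("participant IDs do not match between tables")
    sp <- spearman_tied(demographics$quickdash, m$accuracy)
    data.frame(side = s, rho = sp$rho, p_value = sp$p_value, n = sp$n)
  })
  do.call(rbind, res)
}
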