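#' Process one synthetic or recorded session through the analysis chain
#'
#' Runs synchronization (calibration detection, lag estimation), realigns
#' the right stream, trims to the interval between the two calibration
#' events, and computes per side: the 1-s activity-counts series, the 4-s
#' epoch feature matrix (after spline resampling to 50 Hz), and the
#' epoch-level annotation labels with binary ground truth.
#'
#' @param session A `synthetic_session` (or a list with the same elements:
#'   anatomical `left`/`right` signals and `left_truth`/`right_truth`
#'   tracks).
#' @param mixed_policy Passed to [binary_truth()].
#' @param entropy_bins Passed to [epoch_features()].
#' @param sync_args List of arguments forwarded to
#'   [synchronize_session()].
#' @return List of class `processed_session` with `sync` and one element
#'   per side holding `features`, `epochs` (label series), `truth`
#'   (binary + retained index), `counts`, `duration_s`.
#' @export
process_session <- function(session, mixed_policy = "exclude",
                            entropy_bins = 16, sync_args = list()) {
  sync <- do.call(synchronize_session,
                  c(list(session$left, session$right), sync_args))
  signals <- list(left = session$left,
                  right = shift_signal(session$right,
                                       -sync$lag_right_vs_left_s))
  out <- list(sync = sync)
  for (side in c("left", "right")) {
    trimmed <- trim_to_calibration(signals[[side]],
                                   session[[paste0(side, "_truth")]], sync)
    counts <- accel_to_counts(trimmed$signal)
    feats <- epoch_features(resample_to_50hz(trimmed$signal),
                            entropy_bins = entropy_bins)
    series <- frames_to_epochs(trimmed$track)
    n_ep <- min(nrow(feats), length(series$labels))
    feats <- feats[seq_len(n_ep), , drop = FALSE]
    series$labels <- series$labels[seq_len(n_ep)]
    out[[side]] <- list(
      features = feats,
      epochs = series,
      truth = binary_truth(series, mixed_policy),
      counts = counts,
      duration_s = signal_duration(trimmed$signal))
  }
  class(out) <- "processed_session"
  out
}

#' Run the full synthetic-cohort validation experiment
#'
#' Simulates a cohort of home sessions (per-session seeds fan out
#' deterministically from the cohort seed; right-sensor clock offsets are
#' drawn uniformly from ±`max_offset_s`), processes every session, trains
#' the epoch classifier on the training sessions' ground-truth epochs, and
#' evaluates on the held-out sessions: per-session/side classification
#' metrics, functional-use summaries for all three estimation methods,
#' cohort mean differences from ground truth, classifier accuracy against
#' the majority-class baseline, and lag-recovery errors. When a
#' per-participant score column is supplied, the tie-corrected Spearman
#' correlation between scores and test-session accuracies is added.
#'
#' @param n_sessions Number of simulated participants (default 10).
#' @param n_train Number of sessions used for training (default 6; the
#'   remainder are the test set, split by session so no participant leaks
#'   across the split).
#' @param seed Cohort seed.
#' @param schedule Session schedule, default [default_protocol_schedule()].
#' @param learner,mixed_policy,entropy_bins,counts_threshold,noise_sd_g
#'   Pipeline parameters (defaults: random forest, exclude mixed epochs,
#'   16 entropy bins, counts threshold 1, 0.02 g sensor noise).
#' @param max_offset_s Half-range of the simulated clock offsets, seconds.
#' @param scores Optional numeric vector (length = number of test
#'   sessions) correlated against test accuracies.
#' @return List of class `cohort_report`: `metrics_table`, `use_table`,
#'   `mean_differences`, `lag_table`, `test_accuracy`,
#'   `baseline_accuracy`, `model`, and optionally `score_correlation`.
#' @export
run_validation_experiment <- function(n_sessions = 10, n_train = 6,
                                      seed = 1L,
                                      schedule = default_protocol_schedule(),
                                      learner = "random_forest",
                                      mixed_policy = "exclude",
                                      entropy_bins = 16,
                                      counts_threshold = 1,
                                      noise_sd_g = 0.02,
                                      max_offset_s = 2,
                                      scores = NULL) {
  stopifnot(n_train >= 1, n_sessions > n_train)
  set.seed(seed)
  offsets <- stats::runif(n_sessions, -max_offset_s, max_offset_s)

  sessions <- vector("list", n_sessions)
  processed <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- session_config(schedule, clock_offset_s = offsets[i],
                          noise_sd_g = noise_sd_g, seed = seed + i)
    sessions[[i]] <- simulate_session(cfg)
    processed[[i]] <- process_session(sessions[[i]],
                                      mixed_policy = mixed_policy,
                                      entropy_bins = entropy_bins)
  }

  train_idx <- seq_len(n_train)
  test_idx <- setdiff(seq_len(n_sessions), train_idx)

  train_x <- NULL; train_y <- integer(0)
  for (i in train_idx) for (side in c("left", "right")) {
    ps <- processed[[i]][[side]]
    train_x <- rbind(train_x, ps$features[ps$truth$retained_index, , drop = FALSE])
    train_y <- c(train_y, ps$truth$binary)
  }
  model <- train_functional_model(train_x, train_y, learner = learner,
                                  seed = seed)

  metrics_rows <- list(); use_rows <- list()
  pooled_pred <- integer(0); pooled_truth <- integer(0)
  for (i in test_idx) for (side in c("left", "right")) {
    ps <- processed[[i]][[side]]
    pred <- predict_epochs(model, ps$features)
    cm <- confusion(pred[ps$truth$retained_index], ps$truth$binary)
    mr <- metrics(cm)
    subj <- sprintf("S_%03d", i)
    metrics_rows[[length(metrics_rows) + 1]] <- data.frame(
      subj_id = subj, side = side, accuracy = mr$accuracy,
      recall = mr$recall, specificity = mr$specificity, f1 = mr$f1)
    ca <- active_minutes_counts(ps$counts, threshold = counts_threshold)
    us <- use_summary(ps$truth$binary, pred, ca$active, ps$duration_s)
    us$subj_id <- subj; us$side <- side
    use_rows[[length(use_rows) + 1]] <- us
    pooled_pred <- c(pooled_pred, pred[ps$truth$retained_index])
    pooled_truth <- c(pooled_truth, ps$truth$binary)
  }
  metrics_table <- do.call(rbind, metrics_rows)
  use_table <- do.call(rbind, use_rows)

  test_accuracy <- mean(pooled_pred == pooled_truth)
  baseline_accuracy <- max(mean(pooled_truth), 1 - mean(pooled_truth))

  lag_table <- data.frame(
    session = seq_len(n_sessions),
    true_offset_s = offsets,
    estimated_lag_s = vapply(processed,
                             function(p) p$sync$lag_right_vs_left_s,
                             numeric(1)))
  lag_table$error_s <- lag_table$estimated_lag_s -
    round(lag_table$true_offset_s * 30) / 30

  report <- list(metrics_table = metrics_table,
                 use_table = use_table,
                 mean_differences = if (length(test_idx) >= 2)
                   cohort_mean_differences(use_table) else NULL,
                 lag_table = lag_table,
                 test_accuracy = test_accuracy,
                 baseline_accuracy = baseline_accuracy,
                 model = model,
                 seed = seed,
                 n_sessions = n_sessions,
                 test_sessions = test_idx)
  if (!is.null(scores)) {
    acc_l <- metrics_table$accuracy[metrics_table$side == "left"]
    acc_r <- metrics_table$accuracy[metrics_table$side == "right"]
    report$score_correlation <- data.frame(
      side = c("left", "right"),
      rho = c(spearman_tied(scores, acc_l)$rho,
              spearman_tied(scores, acc_r)$rho))
  }
  class(report) <- "cohort_report"
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d sessions (test: %s) | test accuracy %.3f (majority baseline %.3f)\n",
    x$n_sessions, paste(x$test_sessions, collapse = ","),
    x$test_accuracy, x$baseline_accuracy))
  print(x$mean_differences)
  invisible(x)
}
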