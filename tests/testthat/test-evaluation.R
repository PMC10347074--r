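test_that("confusion counts match a brute-force enumeration", {
  expect_equal(unclass(confusion(c(1, 0, 1), c(1, 0, 1)))[c("TP", "FP", "FN", "TN")],
               list(TP = 2L, FP = 0L, FN = 0L, TN = 1L),
               ignore_attr = TRUE)
  expect_equal(confusion(c(1, 1), c(0, 0))$FP, 2)
  # exhaustive: all 2^4 x 2^4 length-4 prediction/truth pairs
  combos <- expand.grid(replicate(4, 0:1, simplify = FALSE))
  for (i in seq_len(nrow(combos))) for (j in seq_len(nrow(combos))) {
    pred <- as.integer(combos[i, ]); truth <- as.integer(combos[j, ])
    cm <- confusion(pred, truth)
    brute <- table(factor(paste0(pred, truth),
                          levels = c("11", "10", "01", "00")))
    expect_identical(c(cm$TP, cm$FP, cm$FN, cm$TN), as.integer(brute))
  }
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metric formulas evaluate as printed", {
  cm <- confusion(c(rep(1, 3), rep(0, 7)),
                  c(1, 1, 0, 1, rep(0, 6)))  # TP=2 FP=1 FN=1 TN=6
  m <- metrics(cm)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$specificity, 6 / 7)
  expect_length(m$degenerate, 0)

  perfect <- metrics(confusion(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unlist(perfect[c("accuracy", "recall", "specificity",
                                "precision", "f1")]),
               rep(1, 5), ignore_attr = TRUE)

  # TP=0 with FN>0 and FP>0: recall=precision=0, f1 degenerate -> 0 + flag
  deg <- metrics(confusion(c(1, 0, 0), c(0, 1, 1)))
  expect_equal(deg$recall, 0)
  expect_equal(deg$precision, 0)
  expect_equal(deg$f1, 0)
  expect_true("f1" %in% deg$degenerate)
})

test_that("accuracy is invariant under class swap; f1 is not", {
  set.seed(8)
  pred <- sample(0:1, 60, replace = TRUE, prob = c(0.3, 0.7))
  truth <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  m <- metrics(confusion(pred, truth))
  m_swap <- metrics(confusion(1 - pred, 1 - truth))
  expect_equal(m_swap$accuracy, m$accuracy)
  expect_false(isTRUE(all.equal(m_swap$f1, m$f1)))
})

test_that("use summaries convert epoch counts to minutes and fractions", {
  # 239 functional truth epochs in a 28.45 min session: the bookkeeping
  # behind a printed 15.93 min / 0.56 row
  us <- use_summary(truth_epochs = rep(1L, 239),
                    mlm_epochs = rep(1L, 296),
                    counts_active = rep(TRUE, round(26.28 * 60)),
                    session_duration_s = 28.45 * 60)
  expect_equal(us$minutes[us$method == "ground_truth"], 239 * 4 / 60)
  expect_equal(us$percent[us$method == "ground_truth"], 0.56,
               tolerance = 0.005)
  expect_equal(us$minutes[us$method == "mlm"], 19.73, tolerance = 0.005)
  expect_equal(us$minutes[us$method == "counts"], 26.28, tolerance = 0.005)
  none <- use_summary(integer(0), integer(0), logical(0), 60)
  expect_equal(none$percent, rep(0, 3))
  full <- use_summary(rep(1L, 15), rep(1L, 15), rep(TRUE, 60), 60)
  expect_equal(full$percent, rep(1, 3))
  expect_error(use_summary(1L, 1L, TRUE, 0), "positive")
})

test_that("cohort mean difference is the mean/SD of per-participant deltas", {
  tab <- data.frame(
    subj_id = rep(c("A", "B"), times = 2),
    side = "left",
    method = rep(c("ground_truth", "mlm"), each = 2),
    percent = c(0.5, 0.6, 0.6, 0.9))
  md <- mean_difference(tab, "mlm", "left")
  expect_equal(md$mean, 0.2)
  expect_equal(md$sd, sd(c(0.1, 0.3)))
  self <- mean_difference(tab, "ground_truth", "left")
  expect_equal(self$mean, 0)
  tab_missing <- tab[-4, ]
  expect_error(mean_difference(tab_missing, "mlm", "left"), "missing participant")
})

test_that("tie-corrected Spearman equals Pearson on mid-ranks", {
  expect_equal(spearman_tied(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_tied(1:8, -(1:8))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(10, 20, 30, 40)
  expect_equal(spearman_tied(x, y)$rho,
               cor(c(1, 2.5, 2.5, 4), 1:4))
  # independent oracle: stats::cor.test with the t approximation
  set.seed(12)
  for (i in 1:5) {
    a <- sample(1:6, 10, replace = TRUE)
    b <- rnorm(10)
    ours <- spearman_tied(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_tied(rep(1, 5), 1:5), "constant")
  expect_error(spearman_tied(1:2, 1:2), "n >= 3")
})
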