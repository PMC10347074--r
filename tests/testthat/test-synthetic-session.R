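test_that("quiet sitting with zero noise is exactly unit gravity", {
  s <- simulate_session(quiet_config(duration_s = 30))
  expect_equal(accel_norm(s$left), rep(1, 900))
  expect_equal(accel_norm(s$right), rep(1, 900))
  expect_true(all(s$left_truth$labels == 1L))
})

test_that("the same config yields bit-identical sessions", {
  cfg <- session_config(short_schedule(), clock_offset_s = 0.4, seed = 99)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
  expect_identical(a$left_truth, b$left_truth)
  # a different seed changes the signal
  c <- simulate_session(session_config(short_schedule(),
                                       clock_offset_s = 0.4, seed = 100))
  expect_false(identical(a$left$x, c$left$x))
})

test_that("schedule bookkeeping: labels and samples follow the blocks", {
  sched <- data.frame(
    activity = c("walking", "functional_bout"),
    duration_s = c(60, 60))
  cfg <- suppressWarnings(session_config(sched, seed = 3))
  s <- simulate_session(cfg)
  lab <- s$left_truth$labels
  # functional fraction of labeled (non-calibration) time is exactly 1/2
  expect_equal(sum(lab == 2L) / sum(lab %in% c(1L, 2L)), 0.5)
  expect_equal(length(s$left$x), 120 * 30)
  expect_equal(n_frames(s$left_truth), 120 * 25)
})

test_that("per-block sample counts are conserved within one sample", {
  cfg <- session_config(short_schedule(adl_s = 61.3, walk_s = 29.7),
                        seed = 5)
  s <- simulate_session(cfg)
  expect_equal(length(s$left$x),
               round(sum(cfg$schedule$duration_s) * 30), tolerance = 1)
  expect_equal(n_frames(s$left_truth),
               round(sum(cfg$schedule$duration_s) * 25), tolerance = 1)
})

test_that("calibration blocks carry 3-5 supra-gravity flexion bursts", {
  cfg <- session_config(short_schedule(), seed = 21)
  s <- simulate_session(cfg)
  ev <- detect_calibration(s$left)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$n_bursts >= 3 & ev$n_bursts <= 5))
  # calibration spans are annotated unknown (category 0)
  expect_true(all(s$left_truth$labels[1:(10 * 25)] == 0L))
})

test_that("activity classes have the intended signal structure", {
  cfg <- session_config(short_schedule(adl_s = 60, walk_s = 60, sit_s = 60),
                        noise_sd_g = 0, seed = 8)
  s <- simulate_session(cfg)
  lab_at <- function(kind) {
    sched <- cfg$schedule
    b <- which(sched$activity == kind)[1]
    bounds <- round(cumsum(c(0, sched$duration_s)) * 30)
    (bounds[b] + 1):bounds[b + 1]
  }
  walk <- lab_at("walking"); fun <- lab_at("functional_bout")
  nrm <- accel_norm(s$left)
  # functional bouts move on all axes and have higher norm variance
  expect_gt(var(nrm[fun]), var(nrm[walk]))
  expect_gt(var(s$left$y[fun]), var(s$left$y[walk]))
  # walking is carried by the anterior-posterior axis around ~1 Hz
  sp <- spec.pgram(s$left$z[walk], plot = FALSE, taper = 0)
  peak_hz <- sp$freq[which.max(sp$spec)] * 30
  expect_gt(peak_hz, 0.8)
  expect_lt(peak_hz, 1.2)
})

test_that("right stream is delayed by the configured clock offset", {
  cfg <- session_config(short_schedule(), clock_offset_s = 0.5, seed = 13)
  s <- simulate_session(cfg)
  ref <- simulate_session(session_config(short_schedule(),
                                         clock_offset_s = 0, seed = 13))
  k <- 15  # 0.5 s at 30 Hz
  n <- length(ref$right$x)
  expect_equal(s$right$x[(k + 1):n], ref$right$x[1:(n - k)])
})

test_that("ground-truth functional minutes follow the epoch formula", {
  mk_session <- function(n_functional, n_other) {
    labels <- c(rep(2L, n_functional * 100), rep(1L, n_other * 100))
    list(left_truth = annotation_track(labels, 25))
  }
  expect_equal(truth_functional_minutes(mk_session(231, 10), "left"), 15.4)
  expect_equal(truth_functional_minutes(mk_session(185, 10), "left"),
               12.33, tolerance = 0.005)
  expect_equal(truth_functional_minutes(mk_session(0, 10), "left"), 0)
})

test_that("negative durations are a configuration error", {
  expect_error(session_config(data.frame(activity = "walking",
                                         duration_s = -5)),
               "positive")
})

test_that("written session CSVs reproduce the in-memory session", {
  cfg <- session_config(short_schedule(), seed = 31)
  s <- simulate_session(cfg)
  dir <- withr::local_tempdir()
  paths <- write_session(s, dir)
  left <- to_anatomical(read_accel_csv(paths[["left"]], "left"))
  expect_equal(left$x, s$left$x, tolerance = 1e-9)
  markers <- read_marker_csv(paths[["markers"]])
  back <- markers_to_track(markers, "left",
                           duration_s = n_frames(s$left_truth) / 25)
  expect_identical(back$labels, s$left_truth$labels)
})
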