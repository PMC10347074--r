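test_that("calibration detection recovers injected blocks within 0.5 s", {
  cfg <- session_config(short_schedule(calibration_s = 12), seed = 2)
  s <- simulate_session(cfg)
  ev <- detect_calibration(s$left)
  expect_equal(nrow(ev), 2)
  # bursts start 1 s into each block; block 2 starts at 12+30+60+20+30+60
  expect_lt(abs(ev$start_s[1] - 1.0), 0.5)
  expect_lt(abs(ev$start_s[2] - 213.0), 0.5)
})

test_that("sessions without detectable calibration raise a sync error", {
  s <- simulate_session(quiet_config(duration_s = 120, noise_sd_g = 0.02))
  expect_error(detect_calibration(s$left), "sync error")
  # threshold above the burst amplitude is equivalent to no bursts
  cfg <- session_config(short_schedule(), seed = 4)
  s2 <- simulate_session(cfg)
  expect_error(detect_calibration(s2$left, threshold_g = 10), "sync error")
  expect_error(detect_calibration(s2$left, threshold_g = 0.9), "exceed 1 g")
})

test_that("lag estimation: zero for identical signals, recovers a made shift", {
  cfg <- session_config(short_schedule(), seed = 6)
  s <- simulate_session(cfg)
  expect_equal(estimate_lag(s$left, s$left)$lag_s, 0)

  cfg2 <- session_config(short_schedule(), clock_offset_s = 0.5, seed = 6)
  s2 <- simulate_session(cfg2)
  est <- estimate_lag(s2$left, s2$right,
                      window_s = c(0, 14))
  expect_equal(est$lag_s, 0.5, tolerance = 1 / 30 + 1e-9)
  expect_false(est$at_boundary)
})

test_that("a shift at the search edge is flagged and flat signals error", {
  # true lag sits exactly on the search edge -> peak at the boundary
  cfg <- session_config(short_schedule(), clock_offset_s = 1, seed = 9)
  s <- simulate_session(cfg)
  est <- estimate_lag(s$left, s$right, max_lag_s = 1, window_s = c(0, 14))
  expect_true(est$at_boundary)
  expect_equal(est$lag_s, 1)
  flat <- simulate_session(quiet_config(duration_s = 30))
  expect_error(estimate_lag(flat$left, flat$right), "flat signal")
})

test_that("lag recovery over 20 seeded sessions has median error <= 1 sample", {
  errors <- sapply(1:20, function(i) {
    off <- stats::runif(1, -2, 2)
    cfg <- session_config(short_schedule(adl_s = 30, walk_s = 15, sit_s = 10),
                          clock_offset_s = off, seed = 3000 + i)
    s <- simulate_session(cfg)
    sync <- synchronize_session(s$left, s$right)
    sync$lag_right_vs_left_s - round(off * 30) / 30
  })
  expect_lte(stats::median(abs(errors)), 1 / 30 + 1e-9)
})

test_that("trimming keeps the interior, stays aligned, and is idempotent", {
  cfg <- session_config(short_schedule(calibration_s = 12), seed = 12)
  s <- simulate_session(cfg)
  sync <- synchronize_session(s$left, s$right)
  tr <- trim_to_calibration(s$left, s$left_truth, sync)
  retained_s <- sync$second_calibration_start_s - sync$first_calibration_end_s
  expect_equal(signal_duration(tr$signal), retained_s, tolerance = 2 / 30)
  # track and signal cover the same span (25 fps vs 30 Hz)
  expect_equal(n_frames(tr$track) / 25, signal_duration(tr$signal),
               tolerance = 2 / 25)
  # idempotence
  tr2 <- trim_to_calibration(tr$signal, tr$track, sync)
  expect_identical(tr2$signal$x, tr$signal$x)
  expect_identical(tr2$track$labels, tr$track$labels)
  # empty interior
  bad <- sync
  bad$second_calibration_start_s <- sync$first_calibration_end_s - 1
  expect_error(trim_to_calibration(s$left, s$left_truth, bad),
               "empty interior")
})

test_that("spot-check drift is near zero for offset-stable sessions", {
  cfg <- session_config(short_schedule(), clock_offset_s = -1.2, seed = 14)
  s <- simulate_session(cfg)
  sync <- synchronize_session(s$left, s$right)
  expect_equal(sync$lag_right_vs_left_s, -1.2, tolerance = 1 / 30 + 1e-9)
  expect_lte(abs(sync$spot_check_drift_s), 1 / 30 + 1e-9)
})
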