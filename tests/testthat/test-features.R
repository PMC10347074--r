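test_that("spline resampling: constant, sine, and ramp behave as expected", {
  n <- 1800
  const <- accel_signal(rep(2, n), rep(0, n), rep(0, n), 30, "left")
  rc <- resample_to_50hz(const)
  expect_equal(length(rc$x), 3000)  # 5/3 of the input length
  expect_equal(rc$x, rep(2, 3000))
  expect_equal(rc$sample_rate_hz, 50)

  t30 <- (0:(n - 1)) / 30
  sine <- accel_signal(sin(2 * pi * 1 * t30), rep(0, n), rep(0, n), 30, "left")
  rs <- resample_to_50hz(sine)
  t50 <- (0:2999) / 50
  expect_lt(max(abs(rs$x - sin(2 * pi * t50)))[1], 0.01)
  expect_equal(max(rs$x), 1, tolerance = 0.01)

  ramp <- accel_signal(3 * t30 + 1, rep(0, n), rep(0, n), 30, "left")
  rr <- resample_to_50hz(ramp)
  expect_equal(rr$x, 3 * t50 + 1, tolerance = 1e-9)

  # 50 Hz input passes through unchanged
  expect_message(same <- resample_to_50hz(rs), "already at 50 Hz")
  expect_identical(same$x, rs$x)
})

test_that("a constant epoch yields the degenerate feature vector", {
  sig <- accel_signal(rep(0, 200), rep(0, 200), rep(1, 200), 50, "left")
  f <- epoch_features(sig)
  expect_equal(nrow(f), 1)
  expect_identical(colnames(f), armuse:::feature_names)
  expect_equal(as.numeric(f[1, ]),
               c(0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0))
})

test_that("entropy estimator hits its closed-form extremes and bounds", {
  # equal occupancy of all 16 bins -> log2(16) bits
  expect_equal(shannon_entropy(rep(1:16, each = 10), 16), 4)
  expect_equal(shannon_entropy(rep(5, 50), 16), 0)
  # invariant under adding a constant (epoch-relative bin edges)
  set.seed(3)
  v <- rnorm(200)
  expect_equal(shannon_entropy(v, 16), shannon_entropy(v + 100, 16))
  for (i in 1:10) {
    h <- shannon_entropy(rnorm(200), 16)
    expect_gte(h, 0)
    expect_lte(h, 4)
  }
})

test_that("epoch means and variances match a brute-force two-pass oracle", {
  set.seed(31)
  sig <- accel_signal(rnorm(600), rnorm(600), rnorm(600), 50, "left")
  f <- epoch_features(sig)
  expect_equal(nrow(f), 3)
  for (e in 1:3) {
    idx <- ((e - 1) * 200 + 1):(e * 200)
    for (ax in c("x", "y", "z")) {
      v <- sig[[ax]][idx]
      m <- sum(v) / 200
      expect_equal(f[e, paste0("mean_", ax)], m, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(f[e, paste0("var_", ax)], sum((v - m)^2) / 200,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    nv <- sqrt(sig$x[idx]^2 + sig$y[idx]^2 + sig$z[idx]^2)
    expect_equal(f[e, "norm_mean"], mean(nv), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(f[e, "norm_min"] <= f[e, "norm_mean"] &&
                  f[e, "norm_mean"] <= f[e, "norm_max"])
  }
})

test_that("min-max scaling maps, clips, and handles constant columns", {
  f <- matrix(c(2, 6, 4), ncol = 1, dimnames = list(NULL, "mean_x"))
  sc <- fit_minmax(f)
  expect_equal(as.numeric(apply_minmax(sc, f)), c(0, 1, 0.5))
  low <- matrix(1, ncol = 1, dimnames = list(NULL, "mean_x"))
  expect_equal(as.numeric(apply_minmax(sc, low)), 0)
  high <- matrix(10, ncol = 1, dimnames = list(NULL, "mean_x"))
  expect_equal(as.numeric(apply_minmax(sc, high)), 1)
  const <- matrix(rep(7, 3), ncol = 1, dimnames = list(NULL, "mean_x"))
  expect_equal(as.numeric(apply_minmax(fit_minmax(const), const)), rep(0, 3))
  expect_error(fit_minmax(matrix(numeric(0), ncol = 0)), "empty")
  # fit+apply on the same set puts minima at 0 and maxima at 1
  set.seed(5)
  sig <- accel_signal(rnorm(2000), rnorm(2000), rnorm(2000), 50, "left")
  feats <- epoch_features(sig)
  scaled <- apply_minmax(fit_minmax(feats), feats)
  expect_equal(unname(apply(scaled, 2, min)), rep(0, 11))
  expect_equal(unname(apply(scaled, 2, max)), rep(1, 11))
})
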