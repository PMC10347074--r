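# Deterministic 60 s test signals (30 Hz) exercising the counts chain:
# gravity, silence, in-band tones, noise, clipping-level movement, a
# sub-deadband tone, bursts, and out-of-band drift. The frozen reference
# counts in fixtures/counts_reference.csv were computed for exactly these
# signals by an independent scipy-based implementation of the published
# counts algorithm (band-pass, 10 Hz decimation, clip, deadband,
# quantisation, epoch sum).
make_counts_oracle_signals <- function() {
  n <- 1800
  fs <- 30
  t <- (0:(n - 1)) / fs
  zero <- rep(0, n)
  sigs <- list()
  mk <- function(x, y = zero, z = zero)
    accel_signal(x, y, z, fs, "left", "anatomical")

  sigs$gravity <- mk(rep(1, n))
  sigs$silence <- mk(zero)
  sigs$tone_x <- mk(1 + 0.5 * sin(2 * pi * 1.5 * t))
  sigs$tones_xyz <- mk(1 + 0.2 * sin(2 * pi * 0.7 * t),
                       0.3 * sin(2 * pi * 1.1 * t),
                       0.15 * sin(2 * pi * 2.3 * t))
  set.seed(1005)
  sigs$white <- mk(1 + stats::rnorm(n, 0, 0.1),
                   stats::rnorm(n, 0, 0.1),
                   stats::rnorm(n, 0, 0.1))
  set.seed(1006)
  bf <- signal::butter(2, c(0.5, 3) / (fs / 2), type = "pass")
  bl <- function(sd) sd * as.numeric(signal::filter(bf, stats::rnorm(n)))
  sigs$bandlimited <- mk(1 + bl(0.3), bl(0.25), bl(0.2))
  sigs$clipping <- mk(1 + 3 * sin(2 * pi * 1 * t))
  sigs$subdeadband <- mk(1 + 0.01 * sin(2 * pi * 1 * t))
  burst <- rep(0, n)
  for (s0 in c(5, 20, 40)) burst[t >= s0 & t < s0 + 1] <- 2
  sigs$bursts <- mk(1 + burst)
  sigs$drift <- mk(1 + 0.5 * sin(2 * pi * 0.05 * t) +
                     0.1 * sin(2 * pi * 1 * t))
  sigs
}

read_counts_reference <- function() {
  utils::read.csv(test_path("fixtures", "counts_reference.csv"),
                  comment.char = "#")
}
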