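# small session configs used across tests
short_schedule <- function(adl_s = 60, walk_s = 30, sit_s = 20,
                           calibration_s = 10) {
  data.frame(
    activity = c("calibration", "walking", "functional_bout", "quiet_sitting",
                 "walking", "functional_bout", "calibration"),
    duration_s = c(calibration_s, walk_s, adl_s, sit_s, walk_s, adl_s,
                   calibration_s))
}

quiet_config <- function(duration_s = 60, noise_sd_g = 0, seed = 1,
                         incidental_rate_hz = 0) {
  suppressWarnings(session_config(
    data.frame(activity = "quiet_sitting", duration_s = duration_s),
    noise_sd_g = noise_sd_g, incidental_rate_hz = incidental_rate_hz,
    seed = seed))
}
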