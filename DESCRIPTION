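Package: armuse
Title: Functional Upper-Limb Use from Bilateral Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to distinguish functional (task-specific) from
    non-functional upper-limb movement in free-living recordings from
    bilateral wrist-worn tri-axial accelerometers. Implements the full
    validation chain: a synthetic-session generator emulating a home-based
    activities-of-daily-living protocol with calibration flexion bursts,
    walking arm-swing and quiet sitting; CSV signal and annotation-marker
    input/output with remapping of sensor axes to the anatomical convention;
    calibration-burst detection, inter-sensor lag estimation and trimming;
    frame-to-epoch majority labelling of video annotations; an activity-counts
    baseline (published 30 Hz band-pass/deadband/quantisation chain with a
    counts-per-second threshold); 4-s epoch feature extraction (per-axis
    means and variances plus mean, variance, minima, maxima and Shannon
    entropy of the acceleration norm) with min-max scaling; a retrainable
    random-forest epoch classifier; and evaluation statistics (confusion
    matrix metrics, functional minutes, percentage functionally active,
    cohort mean differences and tie-corrected Spearman correlation),
    together with the published per-participant cohort tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
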