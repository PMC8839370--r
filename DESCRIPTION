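Package: gaitreliab
Title: IMU-Based Gait Assessment and Test-Retest Reliability for Stroke
    Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes three-sensor (both feet and low back) inertial
    measurement unit recordings of two-minute walking assessments into a
    catalogue of 166 gait features, and quantifies their test-retest
    reliability. Includes a synthetic-gait simulator with known ground
    truth, signal preprocessing (resampling, gyroscope bias correction,
    stationary-period trimming), quaternion sensor fusion with gravity
    removal, a stride-detection algorithm robust to slow and asymmetric
    gait with false-negative and false-positive repair passes, zero-
    velocity-update stride-length reconstruction, low-back event detection
    by foot-informed template matching, spatio-temporal, frequency,
    complexity and asymmetry feature extraction, and reliability
    statistics (ICC(2,1) with 95% confidence intervals, SEM, MDC and
    relative MDC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
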