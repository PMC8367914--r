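Package: threatgaze
Title: Scanpath-Length Indices of Human Threat Conditioning from Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw eye-tracker gaze samples into spherical scan speed
    via great-circle (Haversine) kinematics, integrates scan speed into a
    windowed scanpath-length statistic anchored to anticipated aversive-event
    onset, and fits a gamma response function used in a general linear
    convolution model of scan speed. Includes fixation distribution analyses
    (center distance, duration, two-sample Kolmogorov-Smirnov tests), the
    statistical battery used to evaluate threat-conditioning measures (paired
    t tests, exactly bias-corrected Hedge's g with BCa bootstrap intervals,
    AIC-based log Bayes factors, sign-based classification accuracy,
    consecutive-pair split-half reliability), and a seeded synthetic gaze
    generator for end-to-end validation without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
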