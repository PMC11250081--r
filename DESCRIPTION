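Package: dscreen
Title: Video-Kinematic Screening for Musician's Dystonia in Pianists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anomaly-detection screening of dystonic piano performance from
    markerless hand-landmark kinematics. Reads MediaPipe-style 21-landmark
    trajectories and 88-key vertical-displacement traces, delimits trials at
    the first/last keystroke, spline-normalizes each trial to a 21 x 3 x 128
    tensor, and trains a seven-layer convolutional autoencoder on healthy
    performances only, flagging trials whose reconstruction error exceeds the
    healthy validation mean plus two standard deviations. Companion tools
    compute per-finger biomechanical function scores (strength, force
    reduction under simultaneous exertion, independence, agility), z-score
    profiles and the left-right asymmetry norm with Mann-Whitney U and
    Benjamini-Hochberg group comparison, and measure temporal-order-judgment
    thresholds with a Bayesian ZEST staircase. A synthetic-data generator
    produces keystroke-locked healthy and dystonic trials, biomechanical
    cohorts and simulated psychophysical observers so the whole pipeline is
    exercisable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
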