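Package: soundjump
Title: Acoustic Measurement of Vertical Jump Height
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures countermovement-jump height from the sound a jump makes.
    Landing and take-off transients are detected in noisy gym audio by two
    binary convolutional neural networks operating on 100 ms slices of a
    128-band Mel spectrogram stacked with its delta and delta-delta features;
    event onsets are then refined with an adaptive short-time-energy threshold,
    and flight time is converted to jump height with ballistic kinematics
    (h = g t^2 / 8). Includes a seeded synthetic-data generator that emulates
    jump recordings in noisy sports facilities (steady low-frequency-weighted
    background, impulsive interference, SNR-controlled mixing), training and
    cross-validation utilities, an evaluation harness with the +/-0.05 s
    false-positive convention, a naive energy baseline for comparison, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
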