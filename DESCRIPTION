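Package: qeegpower
Title: Mobile QEEG Spectral Band Power Analysis with BIC Bayes Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantitative EEG (QEEG) band-power
    experiments recorded with mobile amplifiers inside and outside the
    laboratory. Generates seeded synthetic multichannel EEG sessions with
    band-structured oscillations, 1/f background, blink and EMG artifacts;
    converts continuous recordings into baseline-corrected overlapping epochs
    with linked-mastoids re-referencing, EOG/amplitude artifact rejection and
    spherical-spline bad-channel interpolation; computes Hamming-window FFT
    band power (theta, alpha, low beta) in decibels at analysis electrodes;
    runs fully-within repeated-measures ANOVAs augmented with
    BIC-approximation Bayes factors, posterior probabilities and Jeffreys
    evidence labels, plus Bonferroni-corrected environmental-covariate
    correlations; and compares observed repeated-measures Hedges' g effect
    sizes against fixed-effect meta-analytic estimates from the laboratory
    literature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
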