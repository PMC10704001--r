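Package: audscreen
Title: Stimulus Synthesis, Screening Rules, and Psychometric Analysis for
    Remote Psychoacoustics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing web-administered psychoacoustic
    experiments. Provides sample-accurate synthesis of classic psychoacoustic
    stimuli (antiphase tone triads and dichotic chirp-in-noise headphone
    checks, harmonic complexes for fundamental-frequency discrimination, gap
    detection markers in band noise, interaural time and level difference
    pairs, and co-modulation masking release noise configurations); trial-list
    construction, response scoring and conditional study-flow evaluation;
    headphone-use and hearing-status screening rules calibrated by a
    two-Gaussian unequal-variance score model with analytic receiver operating
    characteristics; Bayesian psychometric-function fitting with a
    beta-binomial observation model and threshold extraction at task-specific
    performance points; bias-corrected standardized mean differences with
    inverse-variance pooling; consonant-confusion matrix analysis with
    agglomerative clustering; and parametric simulated observers and cohorts
    for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
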