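Package: psynorm
Title: Adaptive Threshold Estimation and Normative Residual Scoring for
    Case-Control Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical machinery for case-control behavioral studies of
    visual recognition: accelerated stochastic approximation staircases
    with monitor-frame quantization, constrained psychometric function
    fitting (fixed guess rate, bounded lapse rate) and inversion to
    criterion presentation times, generalized linear mixed model ladders
    compared by likelihood-ratio tests, and cross-validated normative
    residual scores compared between groups with nonparametric tests.
    Includes a synthetic cohort and trial-log generator emulating 2AFC
    and 4AFC recognition experiments, so every stage of the pipeline can
    be exercised and validated end to end without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
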