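Package: gazeperim
Title: Eye-Movement Threshold Perimetry Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free implementation of an eye-movement threshold
    perimeter: ZEST Bayesian threshold estimation on a modified 24-2 visual
    field grid, gaze-contingent tangent-screen stimulus geometry, saccadic
    hit/miss response classification, simulated observers with a parametric
    hill of vision and frequency-of-seeing behaviour, a full session runner
    with catch and refixation trials, and the associated analysis layer
    (mean sensitivity, Bland-Altman repeatability, BCa bootstrap intervals,
    repeatability-difference tests, pointwise comparisons, normative tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
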