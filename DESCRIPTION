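Package: rtcal
Title: Post-Projection Calibration of Liquid Chromatography Retention Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers experimental and predicted retention times (RT) between
    liquid chromatography methods by Gaussian-process projection on shared
    calibrant molecules, and calibrates the projections against a
    reference-projected RT (RePRT) derived from a locally run reference
    method, removing the systematic error introduced by differences in LC
    setup (column, mobile phase, gradient). Includes self-organizing-map
    classification of retention behavior for calibrant selection,
    elution-time-relative error metrics, a single-hidden-layer QSRR
    regressor for structure-based RT prediction, RT-based filtering and
    ranking of annotation candidates, and a synthetic multi-method RT data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
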