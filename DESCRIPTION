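Package: bmiadjust
Title: Ethnic-Specific BMI Adjustment and Child Weight Status Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for child body-mass-index (BMI) surveillance in the style of the
    English National Child Measurement Programme (NCMP). Converts BMI to growth-reference
    centiles via the LMS (skewness-median-coefficient-of-variation) method, applies and
    derives ethnic-specific BMI adjustments that standardise the BMI-body-fatness
    relationship of South Asian and Black children to the White reference, classifies
    weight status under population and clinical centile thresholds, summarises prevalences
    with Wilson confidence intervals and rank-based tests, ranks local-authority areas
    before and after adjustment, and simulates NCMP-like populations and deuterium-style
    body-composition calibration datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
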