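Package: anthropoage
Title: Anthropometry-Based Biological Age from Gompertz Mortality Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates AnthropoAge, a biological-age proxy obtained by
    matching the cumulative distribution functions of two sex-stratified
    Gompertz proportional-hazards mortality models (chronological age only
    versus chronological age plus body-mass index and waist-to-height
    ratio), and AnthropoAgeAccel, the residual age acceleration after
    regressing AnthropoAge on chronological age. Includes a synthetic
    multi-study longitudinal cohort generator with known ground truth,
    benchmark body-shape indices (BRI, WWI, ABSI), inverse-probability-of-
    censoring-weighted discrimination metrics (Uno's c-statistic,
    time-dependent AUC), decision curve analysis, weighted stratified Cox
    models, generalized estimating equations with AR(1) working
    correlation and QIC model comparison, and an end-to-end validation
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    lme4
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    sandwich,
    withr,
    jsonlite
Config/testthat/edition: 3
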