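Package: cfcentile
Title: Disease-Specific Reference Percentile Charts for Lung Function and
    Nutrition in Cystic Fibrosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds cystic-fibrosis-specific reference percentile charts for
    FEV1 (forced expiratory volume in one second) and body mass index from
    patient-registry data.  Conditional quantiles from the 1st to the 99th
    percentile are fitted by quantile regression on cubic B-spline bases in
    age and height, separately by sex, using an interior-point linear
    programming solver for the pinball loss.  Includes a seeded synthetic
    registry generator with closed-form ground-truth quantiles, a correction
    for registries reporting the best annual FEV1 instead of an unselected
    measurement, referencing against healthy standards (prediction-equation
    percent predicted and LMS z-scores), bootstrap confidence bands,
    chart-versus-chart area-under-curve bootstrap tests, Bonferroni-adjusted
    group median-percentile comparisons, and percentile-rank lookup for
    individual patients.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    splines,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
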