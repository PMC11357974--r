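Package: sclcpheno
Title: Claims-Based Phenotyping of Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Develops and validates deterministic, treatment-based computable
    phenotypes that separate small cell from non-small cell lung cancer in
    administrative claims, where ICD-10-CM diagnosis codes cannot make the
    distinction. Provides a synthetic linked registry-claims data generator
    calibrated to published utilization patterns, cohort construction with
    index dates, enrollment lookback and censoring, an exploration-phase
    screen for discriminating procedure codes, a boolean rule engine over
    windowed code-set exposures, and diagnostic-accuracy reporting
    (sensitivity, specificity, PPV, NPV) with small-cell count suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
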