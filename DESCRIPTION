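Package: cardioreclass
Title: Carotid Plaque Phenotypes and Cardiovascular Risk Reclassification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how an imaging-derived marker of subclinical
    atherosclerosis (carotid plaque presence and count) changes cardiovascular
    risk prediction. Provides a synthetic-cohort simulator with proportional
    hazards outcomes, object-detection evaluation metrics (IoU, confusion
    matrix, precision/recall, mAP@50), Pooled Cohort Equations absolute-risk
    scoring with eligibility filtering and cohort recalibration, the
    multiplication-factor method for folding a new marker into an absolute
    risk score, censoring-aware reclassification statistics (categorical and
    category-free NRI, IDI, C-index comparison), calibration assessment
    (Greenwood-Nam-D'Agostino test, integrated calibration index),
    descriptive prevalence tests, and two-sample summary-statistics Mendelian
    randomization estimators, orchestrated by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
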