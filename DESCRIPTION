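Package: doifusion
Title: Composite Ultrasound/MRI Depth-of-Invasion Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for preoperative depth-of-invasion (DOI) analysis in tongue
    squamous cell carcinoma: agreement of ultrasound- and MRI-derived DOI with
    pathological DOI (Pearson correlation, simple linear regression,
    Bland-Altman analysis with a proportional-bias test), ROC prediction of
    cervical lymph-node metastasis with Youden cutoff selection, and a
    composite us/mrDOI biomarker built by a percentile-grid search over
    switching thresholds. Includes a calibrated synthetic-cohort generator
    (piecewise measurement-error model and Gaussian-copula variant) so every
    stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
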