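Package: oplsrisk
Title: OPLS-DA Discrimination and Ensemble Risk Prediction for Plasma
    Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical workflow for NMR plasma metabolomics of pancreatic
    cancer staging: preprocessing of metabolite concentration profiles
    (exclusion filtering, total-area normalization, autoscaling), from-scratch
    PCA, PLS-DA and two-class OPLS-DA with component selection, Monte-Carlo
    cross-validation and label-permutation testing, Wilcoxon/Benjamini-
    Hochberg univariate screening with fold changes and cross-comparison
    biomarker-panel construction, random-forest ROC panel assessment, and an
    ensemble vote-ratio scheme that classifies recent-onset-diabetes samples
    as at risk of pancreatic pathology.  Includes a seeded synthetic-cohort
    generator emulating the assumed data structure so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pROC,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
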