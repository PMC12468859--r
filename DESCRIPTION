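Package: lipidscreen
Title: Plasma Lipidomics Biomarker Screening and Diagnostic Panel Evaluation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for discovering and evaluating plasma lipid biomarker
    panels that separate pancreatic cancer (PC) patients from healthy (NM)
    controls. Provides rank-based ROC/AUC and confusion metrics, cross-species
    matching of non-targeted metabolomic features by accurate mass and
    retention time, internal-standard normalization and missingness exclusion
    rules for targeted MRM lipid panels, a three-cohort AUC concordance filter
    with batch-effect flagging, cumulative-marker logistic-regression panel
    evaluation with and without the CA19-9 covariate, and a seeded synthetic
    plasma-lipidome generator so the entire pipeline runs and validates
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    e1071,
    withr,
    yaml
Config/testthat/edition: 3
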