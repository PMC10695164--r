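Package: szrecur
Title: Seizure-Recurrence Phenotyping and Prediction on Synthetic EHR and Claims Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study prediction of seizure recurrence after an initial
    seizure-like event in children from routinely collected data. Provides a
    seeded synthetic generator for longitudinal pediatric EHR and
    administrative-claims cohorts (coded encounters, medications, procedures,
    clinical notes); temporal inclusion criteria around an index seizure-like
    encounter; an expert-style composite recurrence label built from seven
    code-based criteria in the two-year outcome window; structured-data
    feature construction (one-year pre-index code counts, log-normalisation,
    prevalence and chi-square feature selection) with elastic-net logistic and
    gradient-boosted-tree baselines; and a clinical-note path with overlapping
    token-window chunking, pluggable note scorers, largest-margin patient
    aggregation and a note-type ablation harness. Evaluation uses patient-level
    five-fold cross-validation with bootstrap confidence intervals for F1 and
    AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
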