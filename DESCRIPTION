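Package: urinomics
Title: Urine Proteomics Biomarker Discovery, Targeted Validation and Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for urinary protein biomarker studies of
    preeclampsia and related pregnancy disorders. Implements discovery-stage
    label-free differential abundance with a centered fold-change z-statistic
    that corrects for global proteinuria shifts, an empirical-Bayes moderated
    t-test with Benjamini-Hochberg adjustment, targeted (parallel reaction
    monitoring) peak integration with dual iRT / reference-protein
    normalization and two-peptide protein roll-up, and screening evaluation by
    ROC curves with detection rate at a fixed false-positive rate. A synthetic
    cohort generator with planted ground truth makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    ape,
    pracma
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
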