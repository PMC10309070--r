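Package: hncbench
Title: Benchmarking Prognostic Survival Models for Head and Neck Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a multi-institutional prognostic
    modelling benchmark for head and neck cancer. Simulates cohorts with the
    tabular structure of radiotherapy EMR registries (demographics, staging,
    HPV status, treatment, primary tumor volume, censored overall survival),
    fits multitask logistic regression (MTLR) survival models -- linear and
    with a single ELU-activated encoder layer -- alongside penalised logistic,
    Cox proportional hazards and volume-only baselines, and evaluates them
    with AUROC, average precision and the concordance index, stratified
    bootstrap confidence intervals, permutation tests, Benjamini-Hochberg
    FDR control, Kaplan-Meier risk stratification, volume-dependence and
    cohort-shift analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
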