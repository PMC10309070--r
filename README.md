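# hncbench

Benchmarking prognostic models for 2-year overall survival in head and
neck cancer, on a fully synthetic cohort that mirrors the structure of a
large radiotherapy registry and of a crowd-sourced modelling challenge:
tabular EMR covariates plus one image-derived feature (gross tumor
volume), right-censored survival, a date-ordered train/test split, frozen
predictions, and blind test-set evaluation.

## Why

Prognostic-model papers in this space keep finding the same two things:
simple models on clinical variables plus tumor volume are very hard to
beat, and metric choice matters enormously at low event prevalence (a
2-year death rate around 0.14 makes AUROC look flattering while average
precision stays honest, with a random baseline equal to the prevalence).
This package packages that whole experimental design — data generation
with known ground truth, the model roster, the metrics, and the
challenge discipline — so the claims can be stress-tested end to end:

* a **discrete-time hazard simulator** with known log-hazard coefficients,
  administrative censoring, and covariate-shift presets for external
  validation (every censored patient has ≥ 2 years of follow-up, so the
  2-year endpoint binarizes without censoring corrections);
* **MTLR** (multitask logistic regression) survival models, linear and
  deep (single ELU layer), hand-implemented with enumeration-verified
  likelihood and gradient;
* **baselines**: ridge logistic regression, ridge Cox, a clinical-subset
  model, a volume-only model, and an mRMR-selected model on a
  volume-coupled synthetic feature block standing in for radiomics;
* **metrics and inference**: AUROC, average precision, Harrell's C-index
  (all oracle-tested against exhaustive enumeration), stratified
  bootstrap CIs, permutation tests, paired model comparison with BH-FDR,
  Kaplan–Meier risk stratification, volume-dependence and cohort-shift
  analyses;
* the published 12-submission **challenge leaderboard** (AUROC/AP/C-index
  with CIs) shipped as data for metric-agreement analyses.

## Worked example

Simulate a cohort, fit a linear MTLR on the earliest-diagnosed 70.6%, and
evaluate the 2-year endpoint on the held-out patients:

```r
library(hncbench)

# simulate a cohort and split it by date of diagnosis
config <- cohort_config(n_patients = 1000, seed = 42)
cohort <- generate_cohort(config)
split <- split_by_date(cohort, train_fraction = 0.706)

# encode covariates with a schema fitted on the training split only
schema <- fit_schema(split$train)
X_train <- encode(split$train, schema)
X_test <- encode(split$test, schema)

# fit a linear MTLR survival model and predict on the held-out patients
model <- fit_mtlr(X_train, split$train$time_months, split$train$event)
pred <- predict_mtlr(model, X_test)
pred
#> <prediction_set> 294 patients, 24 timepoints

# evaluate the 2-year endpoint and the survival ranking
y_test <- binarize_outcome(split$test)
stratified_bootstrap_ci(auroc, pred$event_prob_2y, y_test,
                        n_boot = 1000, seed = 1)
#> 0.648 [0.552-0.740] (1000 bootstrap replicates)
average_precision(pred$event_prob_2y, y_test)
#> [1] 0.2449584
c_index(pred$risk_score, split$test$time_months, split$test$event)
#> [1] 0.6261674
```

The full benchmark — seven models, frozen predictions, blind evaluation,
ranking with CIs and significance tests — is one call:

```r
res <- run_challenge(challenge_config())
res$report
```

## Analysis workflow

The repository is organised as an analysis workflow: numbered driver
scripts under `analysis/` run the study over the package code in `R/`,
writing small tables to `results/` and large intermediates to `scratch/`.
Run them in order from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R          # cohort + summary table
Rscript analysis/02_run_challenge.R            # train roster, blind-evaluate
Rscript analysis/03_external_validation.R      # covariate-shifted cohorts
Rscript analysis/04_volume_and_stratification.R# volume dependence, KM strata
Rscript analysis/05_metric_agreement.R         # leaderboard + random baselines
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the data
generator and its one-time calibration, the MTLR likelihood and its
penalties, the baselines and tuning protocol, every metric's convention
(tie handling, censoring exclusions, add-one smoothing), and the default
parameter values with their rationale.
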