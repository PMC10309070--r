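---
title: "Methods: survival models, metrics and the benchmark protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival models, metrics and the benchmark protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hncbench benchmarks prognostic models for 2-year overall survival in head
and neck cancer on a fully synthetic cohort that mirrors the structure of a
large radiotherapy registry: tabular EMR covariates, a single image-derived
feature (gross tumor volume), right-censored survival times, a date-ordered
train/test split, and a crowd-sourced-challenge evaluation protocol (frozen
predictions, blind test-set evaluation, AUROC ranking with bootstrap CIs).
This vignette documents the modelling choices, the default parameter values
and why they were chosen, and the numerical details.

## The synthetic cohort generator

Patients are drawn i.i.d. from per-variable distributions
(`default_covariate_specs()`): age, sex, T/N/overall stage, disease site,
performance status, HPV status (with an explicit "Not tested" level), dose,
chemotherapy, and a log-normal tumor volume (median about 15 cc). Survival
follows a discrete-time hazard over monthly intervals,

$$h_k(x) = \min\{1,\; h_{0k}\, e^{\beta \cdot x}\},$$

with ground-truth log-hazard effects (`default_true_coefficients()`) whose
signs follow established prognosis: higher stage, worse performance status,
HPV negativity and larger volume increase the hazard. The last month of the
240-month grid is absorbing, so every patient has a death time; a
`censoring_rate` fraction then receives an administrative censoring time
drawn uniformly on [24, 84] months. Because censoring never occurs before
24 months, every censored patient has at least two years of follow-up, so
2-year survival can be binarized without any censoring correction
(`binarize_outcome()` treats a violation as an error, not a silent drop).

**Calibration of the baseline hazard.** The default
`baseline_hazard = rep(0.0018, 240)` was calibrated once, numerically, so
that combined with the default covariate effects the marginal 2-year event
fraction is close to 0.14 and roughly 40% of patients end censored — the
regime the benchmark is designed to stress (strong class imbalance). This
is a one-time design calibration, not a per-run fitted quantity.

**Default cohort size and split.** `n_patients = 2552` with
`train_fraction = 0.706` yields a 1,802 / 750 date-ordered split. The split
uses a random `diagnosis_index` as a stand-in for date of diagnosis; the
test patients are always the latest-diagnosed block, so no model sees
patients diagnosed after the training cutoff.

**Covariate shift.** `apply_shift()` replaces distribution descriptors of
selected variables while keeping the ground-truth coefficients, emulating
an external cohort from a different population that shares the same
outcome model. Three presets ship with the package (site mix,
oropharynx-only with higher HPV positivity, HPV-negative-enriched); the
magnitudes are illustrative, not estimates of any real institution.

**Synthetic image features.** True radiomics are out of scope; the
`mrmr_feature_model` instead consumes a block of `p` features
`volume_coupling * z + noise_sd * e` with `z` standardised log volume —
features that are partly redundant with volume and partly noise, which is
the documented failure mode of engineered image features whose prognostic
signal is largely volume. At the default `volume_coupling = 0.6`,
`noise_sd = 1` the per-feature Spearman correlation with volume is about
0.5.

**Limitations.** Covariates are drawn independently (no stage-site
correlation), hazards are proportional by construction, and censoring is
purely administrative. The generator is a test harness for the evaluation
machinery, not an epidemiological model; none of its numbers should be
read as clinical estimates.

## MTLR: multitask logistic regression

The time axis is discretised into $K$ intervals with boundaries
$\tau_1 < \dots < \tau_K$ (default: 24 monthly intervals). A death in
interval $k$ is the monotone indicator sequence $y_j = 1\{t \le \tau_j\}$
with unnormalised log-score

$$s_k(x) = \sum_{j \ge k} (w_j \cdot z + b_j),$$

and the survive-everything sequence scores 0; softmax over the $K+1$
scores gives the sequence probabilities, hence a full survival curve
$S(\tau_k) = \sum_{m > k} p_m$ per patient. Censored patients contribute
the log of the tail mass $\sum_{m > j} p_m$ over all sequences consistent
with surviving their censoring interval $j$ (a patient censored past the
grid contributes $\log p_{K+1}$). The penalty

$$\frac{\lambda_s}{2}\sum_k \lVert w_{k+1} - w_k \rVert^2 +
  \frac{\lambda_r}{2}\sum_k \lVert w_k \rVert^2$$

smooths adjacent-interval weights and bounds their norms.

Two variants are provided. The **linear** variant ($z = x$) has a concave
penalised log-likelihood and is maximised by full-batch L-BFGS-B with the
analytic gradient; fits from different starts agree in objective value,
which the tests assert. The **deep** variant passes $x$ through one
ELU-activated layer (`hidden_width`, default 32) and is trained by Adam on
minibatches with early stopping on a held-out 20% of the training split;
its seed fixes the initialisation, the minibatch order and the validation
split, making the fit bit-reproducible.

Predictions expose three quantities: the survival curve, the 2-year event
probability $1 - S(\tau_{24})$ (the binary-task score), and a scalar risk
score $\sum_k (1 - S(\tau_k))$ — the discrete expected number of intervals
spent dead, which is strictly increasing in every interval's death
probability and serves as the C-index ranking score.

**Default penalties.** `lambda_smooth = 100`, `lambda_ridge = 1` were
chosen once by 5-fold cross-validated grid search on the default simulated
cohort — the same tuning protocol the baselines use — and then fixed as
package defaults. A strong smoothness penalty is appropriate for monthly
intervals: with 24 narrow intervals the per-interval weights are poorly
identified individually and only their smooth trajectory matters.

## Baselines

* `logistic_emr` — L2-penalised logistic regression on the one-hot-encoded
  EMR variables; ridge strength tuned on {0.1, 1, 10, 100} by stratified
  5-fold CV (validation AUROC), ties broken toward stronger regularisation.
* `cox_emr` — L2-penalised Cox proportional hazards (Breslow ties) on the
  same encoding; its linear predictor is both the risk score and (being a
  monotone transform of 2-year risk under proportional hazards) the binary
  score.
* `clinical_baseline` — logistic regression on the five-variable clinical
  subset (age, sex, T stage, N stage, HPV status).
* `volume_only` — a single-covariate model on standardised log tumor
  volume, the strongest simple baseline by design of the generator.
* `mrmr_feature_model` — greedy mRMR selection on the synthetic feature
  block followed by ridge logistic regression; the feature count and ridge
  strength are tuned jointly by the same CV protocol.

Both GLM fits go through glmnet with a single ridge value
(`lambda = l2_strength / n`, `standardize = FALSE`, `thresh = 1e-12`), so
`l2_strength` is on the summed-log-likelihood scale and the fits converge
to the unpenalised MLE as `l2_strength` goes to 0 (asserted against `glm()`
and `coxph()` in the tests).

**mRMR variant.** The difference criterion — relevance (mutual information
of the feature with the outcome) minus mean redundancy (mean MI with the
already-selected features) — with MI estimated on equal-frequency 8-bin
discretised features. The variant choice is isolated inside
`mrmr_select()` so a quotient criterion could be swapped in.

## Metrics and inference

* **AUROC** by the Mann–Whitney rank formula with half credit for ties.
* **Average precision** as the threshold sum $\sum_n (R_n - R_{n-1}) P_n$
  with tied scores grouped at a single threshold. Its random baseline is
  the prevalence, which is what makes it informative at 0.14 prevalence
  where AUROC is not. Note the finite-sample mean of a random ranker sits
  slightly *above* the prevalence (about $(1-\pi)/(n_{pos}+1)$).
* **Harrell's C-index** over comparable pairs ($t_i < t_j$, patient $i$
  observed to die), half credit for tied risks; pairs with equal times or a
  censored earlier time are excluded. The binary metrics are deliberately
  *not* censoring-corrected: the inclusion rule makes 2-year labels exact.
* **Stratified bootstrap** percentile CIs (default 95%), resampling within
  outcome strata so every replicate keeps the class or event balance.
* **Permutation tests** against the random-guessing null with add-one
  smoothing, $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$, so
  p is never exactly 0.
* **Model comparison** by a shared-replicate paired bootstrap t-test on
  per-replicate AUROC differences (one-sided), BH-FDR-corrected across the
  non-best models. Identical score vectors return p = 1 by convention.
* **Cohort shift** by per-variable chi-squared tests with BH-FDR at 5%;
  cells with small expected counts warn rather than silently switching to
  an exact test.

`n_boot = 500` and `n_perm = 500` are the challenge defaults — enough for
stable 95% percentile intervals and a p-value floor of about 0.002 while
keeping a full 7-model evaluation around two minutes on one CPU; both are
configurable where more precision is needed.

## The challenge protocol

`run_challenge()` wires the stages together: simulate, split by date,
encode with schemas fitted on the training split only, train the roster,
**freeze** the test predictions, then evaluate. `evaluate_challenge()`
refuses unfrozen predictions, and `predict_challenge_models()` drops the
outcome columns before any model sees the data — two mechanical guards for
the blind-evaluation discipline. Models are ranked by AUROC with AP as the
tie-break, mirroring the published leaderboard's convention, and each
model's AUROC is compared to the best model's.

Every stage derives its own RNG stream from the master seed via fixed
offsets (`stage_seed()`), so the whole run is bit-reproducible and changing
one stage's stream does not silently shift another's.

## Numerical choices

* Softmax and log-likelihood use max-subtraction (log-sum-exp) so scores of
  any magnitude are safe.
* The C-index uses chunked pair enumeration (512-row blocks), keeping
  memory bounded at large n while matching exhaustive enumeration exactly.
* L-BFGS-B runs with `factr = 1e7`; at the default penalties this reaches
  gradient norms below 0.05 on the full cohort in about a minute at
  n = 10,000.
* Serialization (models, schemas, selections) is JSON with full numeric
  precision (`digits = NA`); round-trips preserve predictions to within
  one unit in the last place.
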