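#!/usr/bin/env Rscript
# Step 4 — tumor-volume dependence and risk stratification.
#
# Quantifies how strongly each model's predictions track tumor volume
# (Spearman rho vs the predicted 2-year event probability) and
# risk-stratifies the test set with the top-ranked model (Kaplan-Meier
# curves, Cox hazard ratio, log-rank test).
#
# Usage: Rscript analysis/04_volume_and_stratification.R

suppressPackageStartupMessages(library(hncbench))

run <- readRDS("scratch/challenge_run.rds")
res <- run$results
test <- res$split$test

binary_preds <- lapply(res$predictions$predictions, `[[`, "binary_score")
perf <- setNames(res$report$ranking$auroc, res$report$ranking$model)
vd <- volume_dependence(binary_preds, test$volume_cc, perf)
write.csv(vd, "results/volume_dependence.csv", row.names = FALSE)
print(vd, row.names = FALSE)

top <- res$report$ranking$model[1]
strat <- km_stratify(binary_preds[[top]], test$time_months, test$event,
                     threshold = 0.5)
cat("\nTop model:", top, "\n")
print(strat)
strat_tab <- data.frame(model = top, hazard_ratio = strat$hazard_ratio,
                        hr_lo = strat$hr_ci[1], hr_hi = strat$hr_ci[2],
                        logrank_p = strat$logrank_p)
write.csv(strat_tab, "results/risk_stratification.csv", row.names = FALSE)
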