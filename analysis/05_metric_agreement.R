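#!/usr/bin/env Rscript
# Step 5 — metric agreement and random-baseline calibration.
#
# Reproduces the two cross-metric agreement correlations from the published
# 12-submission leaderboard, and calibrates the random-guessing baselines
# (mean AP -> prevalence, mean AUROC -> 0.5) by Monte-Carlo at the study
# prevalence of 0.14 and test-set size of 750.
#
# Usage: Rscript analysis/05_metric_agreement.R [seed]

suppressPackageStartupMessages(library(hncbench))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

lb <- challenge_leaderboard()
ag <- metric_agreement(lb, metrics = c("auroc", "ap", "c_index"))
write.csv(ag, "results/metric_agreement.csv", row.names = FALSE)
print(ag, row.names = FALSE)

set.seed(seed)
reps <- vapply(seq_len(1000), function(r) {
  labels <- rbinom(750, 1, 0.14)
  if (sum(labels) == 0) labels[1] <- 1L
  scores <- runif(750)
  c(ap = average_precision(scores, labels), auroc = auroc(scores, labels))
}, numeric(2))
baseline <- data.frame(metric = c("mean_random_ap", "mean_random_auroc"),
                       value = c(mean(reps["ap", ]), mean(reps["auroc", ])),
                       n_replicates = 1000)
write.csv(baseline, "results/random_baselines.csv", row.names = FALSE)
print(baseline, row.names = FALSE)
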