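#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the default 2,552-patient synthetic head-and-neck cohort, splits
# it by date of diagnosis (70.6% / 29.4%, emulating a 1,802 / 750 split),
# and records the cohort-level descriptive statistics. The full patient
# table goes to scratch/ (an intermediate); the summary table to results/.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressPackageStartupMessages(library(hncbench))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- challenge_config(cohort = cohort_config(seed = seed), seed = seed)
cohort <- generate_cohort(cfg$cohort)
split <- split_by_date(cohort, cfg$train_fraction)
y <- binarize_outcome(cohort, cfg$horizon_months)

write_cohort(cohort, "scratch/cohort.csv")

summary_tab <- data.frame(
  statistic = c("n_patients", "n_train", "n_test", "event_rate_2y",
                "censoring_fraction", "median_volume_cc",
                "hpv_positive_fraction", "median_followup_censored_months"),
  value = c(nrow(cohort), nrow(split$train), nrow(split$test), mean(y),
            mean(cohort$event == 0), median(cohort$volume_cc),
            mean(cohort$hpv_status == "Positive"),
            median(cohort$time_months[cohort$event == 0])))
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)
print(summary_tab, row.names = FALSE)
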