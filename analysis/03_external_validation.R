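#!/usr/bin/env Rscript
# Step 3 — external validation on covariate-shifted cohorts.
#
# Applies the frozen models from step 2 to three shifted external cohorts
# (disease-site mix, oropharynx-only with higher HPV positivity,
# HPV-negative-enriched), evaluates blind, and tests each covariate's
# distribution shift against the internal test set (chi-squared, BH-FDR 5%).
#
# Usage: Rscript analysis/03_external_validation.R

suppressPackageStartupMessages(library(hncbench))

run <- readRDS("scratch/challenge_run.rds")
cfg <- run$config
res <- run$results

ext <- run_external_validation(res$trained, res$split$test, cfg)
saveRDS(ext, "scratch/external_validation.rds")

report_challenge(res, external = ext, outdir = "results/challenge",
                 config = cfg)
for (nm in names(ext)) {
  cat("==", nm, "==\n")
  print(ext[[nm]]$report)
  print(ext[[nm]]$shift_test, row.names = FALSE)
}
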