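#!/usr/bin/env Rscript
# Step 2 — train the model roster and blind-evaluate on the held-out split.
#
# Runs the full challenge protocol: simulate, split by diagnosis date,
# generate the volume-coupled synthetic feature block, train all seven
# roster models on the training split only, freeze the test predictions,
# then evaluate. The run object is cached in scratch/ for the later steps;
# ranking and manifest tables go to results/challenge/.
#
# Usage: Rscript analysis/02_run_challenge.R [seed]

suppressPackageStartupMessages(library(hncbench))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("scratch", showWarnings = FALSE)

cfg <- challenge_config(cohort = cohort_config(seed = seed), seed = seed)
res <- run_challenge(cfg)
saveRDS(list(config = cfg, results = res), "scratch/challenge_run.rds")

report_challenge(res, external = NULL, outdir = "results/challenge",
                 config = cfg)
print(res$report)
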