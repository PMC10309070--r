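test_that("AUROC matches exhaustive pair counting, including ties", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- sample(seq_len(6), n, replace = TRUE) / 6  # frequent ties
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
  # perfect and inverted separation
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(auroc(rep(1, 4), c(0, 0, 1, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("average precision matches the threshold-sum oracle", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1L
    scores <- sample(seq_len(5), n, replace = TRUE) / 5
    expect_equal(average_precision(scores, labels),
                 ap_threshold_steps(scores, labels), tolerance = 1e-12)
  }
  # perfect ranking gives AP 1; constant scores give the prevalence
  expect_equal(average_precision(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(average_precision(rep(1, 10), c(rep(0, 7), rep(1, 3))), 0.3)
  expect_error(average_precision(1:3, c(0, 0, 0)), "no positive")
})

test_that("C-index matches exhaustive pair enumeration and handles censoring", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    risk <- sample(seq_len(5), n, replace = TRUE)
    time <- sample(seq_len(8), n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (sum(event == 1 & time < max(time)) == 0) {
      event[which.min(time)] <- 1L
    }
    expect_equal(c_index(risk, time, event), cindex_pairs(risk, time, event),
                 tolerance = 1e-12)
  }
  # chunking path: large n agrees with the oracle on a subsample identity
  set.seed(4)
  n <- 1200  # spans multiple 512-chunks
  risk <- rnorm(n)
  time <- rexp(n) + 0.01
  event <- rbinom(n, 1, 0.5)
  sub <- 1:40
  expect_equal(c_index(risk[sub], time[sub], event[sub]),
               cindex_pairs(risk[sub], time[sub], event[sub]),
               tolerance = 1e-12)
  # perfect concordance
  expect_equal(c_index(5:1, 1:5, rep(1, 5)), 1)
  expect_error(c_index(c(1, 2), c(3, 3), c(1, 1)), "no comparable")
})

test_that("stratified bootstrap preserves class balance and covers truth", {
  set.seed(5)
  n <- 200
  labels <- c(rep(1L, 40), rep(0L, 160))
  scores <- rnorm(n, mean = labels)
  res <- stratified_bootstrap_ci(auroc, scores, labels, n_boot = 200,
                                 seed = 9)
  expect_s3_class(res, "metric_result")
  expect_equal(res$estimate, auroc(scores, labels))
  expect_length(res$replicates, 200)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  # reproducible in the seed
  res2 <- stratified_bootstrap_ci(auroc, scores, labels, n_boot = 200,
                                  seed = 9)
  expect_identical(res$replicates, res2$replicates)
  # survival outcome path
  time <- rexp(n) + 0.01
  event <- rbinom(n, 1, 0.6)
  rs <- stratified_bootstrap_ci(c_index, rnorm(n),
                                list(time_months = time, event = event),
                                n_boot = 50, seed = 2)
  expect_true(is.finite(rs$estimate))
})

test_that("permutation test p-values are smoothed and sided correctly", {
  set.seed(6)
  labels <- rbinom(100, 1, 0.3)
  labels[1:2] <- c(0L, 1L)
  # informative scores: small p, but never exactly 0
  scores <- rnorm(100, mean = labels * 2)
  pt <- permutation_test(auroc, scores, labels, n_perm = 199, seed = 3)
  expect_equal(pt$p_value, 1 / 200, tolerance = 1e-12)
  expect_equal(pt$observed, auroc(scores, labels))
  # uninformative scores: p far from significant
  pt0 <- permutation_test(auroc, rnorm(100), labels, n_perm = 199, seed = 3)
  expect_gt(pt0$p_value, 0.05)
  expect_error(permutation_test(auroc, scores, labels, n_perm = 0), "n_perm")
})

test_that("model comparison detects dominance and respects identity", {
  set.seed(7)
  n <- 300
  labels <- rbinom(n, 1, 0.3)
  labels[1:2] <- c(0L, 1L)
  good <- rnorm(n, mean = 2 * labels)
  bad <- rnorm(n)
  cmp <- compare_models(good, bad, labels, n_boot = 200, seed = 4)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$mean_diff, 0)
  # identical scores: no evidence of superiority by convention
  same <- compare_models(good, good, labels, n_boot = 50, seed = 4)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_diff, 0)
  expect_error(compare_models(good, bad[-1], labels), "same patients")
})

test_that("BH adjustment matches the step-up definition", {
  set.seed(8)
  for (i in 1:50) {
    m <- sample(3:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    res <- fdr_adjust(p, q)
    expect_identical(res$rejected, bh_reject_direct(p, q))
    expect_identical(res$adjusted, p.adjust(p, "BH"))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("KM stratification separates a prognostic score", {
  co <- generate_cohort(tiny_config(n = 1500, seed = 10))
  cfg <- tiny_config(n = 1500, seed = 10)
  prob <- plogis(true_linear_predictor(co, cfg))
  strat <- km_stratify(prob, co$time_months, co$event, threshold = 0.7)
  expect_s3_class(strat, "stratification_result")
  expect_gt(strat$hazard_ratio, 1)
  expect_lt(strat$logrank_p, 0.01)
  expect_setequal(unique(strat$group), c(0L, 1L))
  expect_error(km_stratify(rep(0.1, 10), 1:10, rep(1, 10)), "empty risk")
})

test_that("volume dependence reports Spearman correlations per model", {
  co <- generate_cohort(tiny_config(n = 500, seed = 11))
  preds <- list(vol = log(co$volume_cc),
                noise = with_seed(1, rnorm(500)))
  vd <- volume_dependence(preds, co$volume_cc,
                          performance = c(vol = 0.6, noise = 0.5))
  expect_equal(vd$spearman_rho[vd$model == "vol"], 1)
  expect_lt(abs(vd$spearman_rho[vd$model == "noise"]), 0.15)
  expect_equal(vd$auroc, c(0.6, 0.5))
  expect_error(volume_dependence(list(a = rep(1, 10)), runif(10)),
               "constant predictions")
})

test_that("cohort shift test controls false positives on identical cohorts", {
  cfg <- tiny_config(n = 2000, seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(tiny_config(n = 2000, seed = 13))
  res <- suppressWarnings(cohort_shift_test(a, b))
  expect_true(all(c("variable", "statistic", "p_value", "p_adjusted",
                    "shifted") %in% names(res)))
  # same data-generating process: no variable should be flagged (FDR 5%
  # allows rare false positives; with 7 variables expect none typically)
  expect_lt(sum(res$shifted), 2)
})

test_that("metric agreement computes pairwise Pearson correlations", {
  tab <- data.frame(auroc = c(0.8, 0.7, 0.6, 0.75),
                    ap = c(0.5, 0.4, 0.3, 0.45),
                    c_index = c(0.78, 0.7, 0.62, 0.74))
  ag <- metric_agreement(tab)
  expect_equal(nrow(ag), 3)
  r <- ag$pearson_r[ag$metric_a == "auroc" & ag$metric_b == "ap"]
  expect_equal(r, cor(tab$auroc, tab$ap))
  expect_error(metric_agreement(tab[1:2, ]), "at least 3")
})

test_that("the shipped leaderboard has 12 ranked submissions", {
  lb <- challenge_leaderboard()
  expect_equal(nrow(lb), 12)
  expect_identical(lb$rank, 1:12)
  # ranked by AUROC (non-increasing)
  expect_true(all(diff(lb$auroc) <= 0))
  expect_true(all(lb$auroc_lo <= lb$auroc & lb$auroc <= lb$auroc_hi))
  expect_true(all(lb$ap_lo <= lb$ap & lb$ap <= lb$ap_hi))
  expect_true(all(lb$c_index_lo <= lb$c_index & lb$c_index <= lb$c_index_hi))
})
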