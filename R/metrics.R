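# Performance metrics and inference: AUROC, average precision, Harrell's
# C-index, stratified bootstrap CIs, permutation tests, paired model
# comparison, BH-FDR, KM risk stratification, volume-dependence and
# cohort-shift analyses.

check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  labels
}

#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney statistic: the probability that a random
#' positive outscores a random negative, with half credit for ties. Random
#' guessing scores 0.5 regardless of prevalence.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision–recall curve)
#'
#' The threshold sum \eqn{AP = \sum_n (R_n - R_{n-1}) P_n} over all distinct
#' score values in decreasing order, with tied scores grouped at a single
#' threshold. Unlike AUROC, AP tracks the positive class only and its random
#' baseline equals the prevalence, making it sensitive to class imbalance.
#'
#' @inheritParams auroc
#' @return AP in (0, 1].
#' @export
average_precision <- function(scores, labels) {
  labels <- check_binary(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    stop("AP undefined: no positive labels", call. = FALSE)
  }
  # group tied scores at one threshold, thresholds in decreasing order
  tp_by_score <- rev(tapply(labels, scores, sum))
  n_by_score <- rev(tapply(labels, scores, length))
  tp <- cumsum(tp_by_score)
  npred <- cumsum(n_by_score)
  recall <- tp / n_pos
  precision <- tp / npred
  sum(diff(c(0, recall)) * precision)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs — patient i observed to die before patient j's
#' time (t_i < t_j, event_i = 1) — the fraction where the predicted risk
#' orders them correctly (r_i > r_j), with half credit for tied risks. Pairs
#' with equal times or where the earlier time is censored are not comparable.
#'
#' @param risk_scores Predicted risk scores (higher = shorter survival).
#' @param time_months Follow-up times.
#' @param event 0/1 event indicators.
#' @return C-index in [0, 1].
#' @export
c_index <- function(risk_scores, time_months, event) {
  n <- length(risk_scores)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  event <- as.integer(event)
  n_comp <- 0
  credit <- 0
  # chunked exhaustive pair enumeration keeps memory bounded for large n
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    comp <- outer(time_months[idx], time_months, `<`) & (event[idx] == 1)
    n_comp <- n_comp + sum(comp)
    credit <- credit +
      sum(outer(risk_scores[idx], risk_scores, `>`) & comp) +
      0.5 * sum(outer(risk_scores[idx], risk_scores, `==`) & comp)
  }
  if (n_comp == 0) {
    stop("C-index undefined: no comparable pairs", call. = FALSE)
  }
  credit / n_comp
}

#' Stratified bootstrap confidence interval for a metric
#'
#' Resamples patients with replacement within outcome strata (preserving the
#' class or event balance in every replicate) and reports the percentile
#' interval of the recomputed metric.
#'
#' @param metric_fn Function `(scores, outcome...) -> scalar`; one of the
#'   package metrics or compatible.
#' @param scores Prediction scores (or risk scores).
#' @param outcome For binary metrics, a 0/1 label vector; for the C-index, a
#'   data frame / list with `time_months` and `event`.
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return A `metric_result` list: `estimate`, `ci_low`, `ci_high`, `n_boot`,
#'   `level`, `replicates`.
#' @export
stratified_bootstrap_ci <- function(metric_fn, scores, outcome,
                                    n_boot = 10000, level = 0.95,
                                    seed = 1L) {
  is_surv <- is.list(outcome) && !is.null(outcome$time_months)
  strata_var <- if (is_surv) as.integer(outcome$event) else
    check_binary(outcome)
  eval_metric <- function(idx) {
    if (is_surv) {
      metric_fn(scores[idx], outcome$time_months[idx], outcome$event[idx])
    } else {
      metric_fn(scores[idx], outcome[idx])
    }
  }
  est <- eval_metric(seq_along(scores))
  strata <- split(seq_along(scores), strata_var)
  if (any(lengths(strata) == 0)) stop("empty stratum", call. = FALSE)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(s) {
        s[sample.int(length(s), length(s), replace = TRUE)]
      }), use.names = FALSE)
      eval_metric(idx)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, level = level, replicates = reps),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%.3f [%.3f-%.3f] (%d bootstrap replicates)\n",
              x$estimate, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Permutation test against the random-guessing null
#'
#' Permutes the outcomes relative to the scores, recomputes the metric, and
#' returns the add-one-smoothed p-value
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perm} + 1)} (for
#' `alternative = "greater"`), so p can never be exactly 0.
#'
#' @inheritParams stratified_bootstrap_ci
#' @param n_perm Number of permutations.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with `p_value`, `observed`, `n_perm`.
#' @export
permutation_test <- function(metric_fn, scores, outcome, n_perm = 1000,
                             alternative = c("greater", "less"),
                             seed = 1L) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  is_surv <- is.list(outcome) && !is.null(outcome$time_months)
  eval_metric <- function(ord) {
    if (is_surv) {
      metric_fn(scores, outcome$time_months[ord], outcome$event[ord])
    } else {
      metric_fn(scores, outcome[ord])
    }
  }
  n <- length(scores)
  obs <- eval_metric(seq_len(n))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) eval_metric(sample.int(n)),
           numeric(1))
  })
  extreme <- if (alternative == "greater") sum(perm >= obs) else
    sum(perm <= obs)
  list(p_value = (1 + extreme) / (n_perm + 1), observed = obs,
       n_perm = n_perm)
}

#' Compare two models' AUROC by a paired bootstrap t-test
#'
#' Draws shared stratified bootstrap replicates of the test patients,
#' computes both models' AUROC on each replicate, and applies a one-sided
#' paired t-test to the per-replicate differences (H1: the first model's
#' AUROC is greater). Identical score vectors give all-zero differences; by
#' convention this returns p = 1 (no evidence of superiority).
#'
#' @param scores_best,scores_other Prediction scores from the two models on
#'   the same patients, in the same order.
#' @param labels 0/1 outcome labels.
#' @param n_boot Number of shared bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `p_value`, `mean_diff`, `n_boot`.
#' @export
compare_models <- function(scores_best, scores_other, labels,
                           n_boot = 1000, seed = 1L) {
  if (length(scores_best) != length(scores_other) ||
      length(scores_best) != length(labels)) {
    stop("score vectors and labels must cover the same patients",
         call. = FALSE)
  }
  labels <- check_binary(labels)
  strata <- split(seq_along(labels), labels)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(s) {
        s[sample.int(length(s), length(s), replace = TRUE)]
      }), use.names = FALSE)
      auroc(scores_best[idx], labels[idx]) -
        auroc(scores_other[idx], labels[idx])
    }, numeric(1))
  })
  if (stats::sd(diffs) == 0) {
    p <- if (mean(diffs) > 0) 0 else 1
  } else {
    p <- stats::t.test(diffs, alternative = "greater")$p.value
  }
  list(p_value = p, mean_diff = mean(diffs), n_boot = n_boot)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]; returns both adjusted p-values
#' and rejection flags at level `q`. Flags are monotone in the raw p-values.
#'
#' @param p_values Raw p-values in [0, 1].
#' @param q Target false discovery rate.
#' @return List with `adjusted` and logical `rejected`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Kaplan–Meier risk stratification
#'
#' Splits patients into low/high-risk groups by thresholding the predicted
#' 2-year event probability (default 0.5), estimates the per-group
#' Kaplan–Meier curves, the Cox hazard ratio of high vs low risk, and the
#' log-rank p-value.
#'
#' @param pred A `prediction_set` or a numeric vector of 2-year event
#'   probabilities.
#' @param time_months,event Observed outcomes.
#' @param threshold Event-probability cutoff for the high-risk group.
#' @return A `stratification_result`: `group` (0 = low, 1 = high risk),
#'   `km_fit` ([survival::survfit] object), `hazard_ratio`, `hr_ci`,
#'   `logrank_p`.
#' @export
km_stratify <- function(pred, time_months, event, threshold = 0.5) {
  prob <- if (inherits(pred, "prediction_set")) pred$event_prob_2y else
    as.numeric(pred)
  group <- as.integer(prob >= threshold)
  if (length(unique(group)) < 2) {
    stop("stratification produced an empty risk group at threshold ",
         threshold, call. = FALSE)
  }
  df <- data.frame(time = time_months, event = as.integer(event),
                   group = group)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  cox <- survival::coxph(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  ci <- exp(stats::confint(cox))
  structure(list(group = group, km_fit = km,
                 hazard_ratio = unname(exp(stats::coef(cox))),
                 hr_ci = unname(ci[1, ]), logrank_p = logrank_p),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("HR (high vs low risk) = %.2f [%.2f-%.2f], log-rank p = %.2g\n",
              x$hazard_ratio, x$hr_ci[1], x$hr_ci[2], x$logrank_p))
  invisible(x)
}

#' Volume dependence of model predictions
#'
#' Spearman rank correlation between each model's predicted 2-year event
#' probability and tumor volume; strongly volume-driven predictors approach
#' rho = 1. Returned alongside an optional performance column for a
#' correlation-vs-performance table.
#'
#' @param predictions Named list of numeric prediction vectors (or
#'   `prediction_set` objects).
#' @param volume_cc Tumor volumes.
#' @param performance Optional named numeric vector (e.g. per-model AUROC) to
#'   attach.
#' @return Data frame with `model`, `spearman_rho` and optionally `auroc`.
#' @export
volume_dependence <- function(predictions, volume_cc, performance = NULL) {
  if (length(volume_cc) < 3) stop("need at least 3 patients", call. = FALSE)
  rho <- vapply(predictions, function(p) {
    v <- if (inherits(p, "prediction_set")) p$event_prob_2y else
      as.numeric(p)
    if (stats::sd(v) == 0) {
      stop("constant predictions: Spearman correlation undefined",
           call. = FALSE)
    }
    stats::cor(v, volume_cc, method = "spearman")
  }, numeric(1))
  out <- data.frame(model = names(predictions), spearman_rho = unname(rho),
                    stringsAsFactors = FALSE)
  if (!is.null(performance)) {
    out$auroc <- unname(performance[out$model])
  }
  out
}

#' Test covariate distribution shift between two cohorts
#'
#' Pairwise chi-squared tests of each shared categorical variable's
#' distribution in cohort A vs cohort B, with Benjamini–Hochberg FDR
#' correction across variables. Cells with expected count below 5 raise the
#' usual chi-squared approximation warning rather than switching to an exact
#' test.
#'
#' @param cohort_a,cohort_b Cohort data frames.
#' @param variables Categorical variables to compare.
#' @param q FDR level.
#' @return Data frame with `variable`, `statistic`, `p_value`, `p_adjusted`,
#'   `shifted` flag.
#' @export
cohort_shift_test <- function(cohort_a, cohort_b,
                              variables = c("sex", "t_stage", "n_stage",
                                            "overall_stage", "disease_site",
                                            "performance_status",
                                            "hpv_status"),
                              q = 0.05) {
  variables <- intersect(variables, intersect(names(cohort_a),
                                              names(cohort_b)))
  if (!length(variables)) stop("no shared variables to compare",
                               call. = FALSE)
  res <- lapply(variables, function(nm) {
    x <- c(as.character(cohort_a[[nm]]), as.character(cohort_b[[nm]]))
    g <- rep(c("A", "B"), c(nrow(cohort_a), nrow(cohort_b)))
    tst <- stats::chisq.test(table(g, x))
    data.frame(variable = nm, statistic = unname(tst$statistic),
               p_value = tst$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- fdr_adjust(out$p_value, q)
  out$p_adjusted <- adj$adjusted
  out$shifted <- adj$rejected
  out
}

#' Agreement between performance measures across models
#'
#' Pearson correlation between metric columns of a per-model results table,
#' quantifying how consistently different metrics rank the same models.
#'
#' @param table Data frame with one row per model and numeric metric columns.
#' @param metrics Columns to correlate (all pairs reported).
#' @return Data frame with `metric_a`, `metric_b`, `pearson_r`.
#' @export
metric_agreement <- function(table,
                             metrics = c("auroc", "ap", "c_index")) {
  metrics <- intersect(metrics, names(table))
  if (nrow(table) < 3) stop("need at least 3 models", call. = FALSE)
  pairs <- utils::combn(metrics, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- table[[pr[1]]]
    b <- table[[pr[2]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("constant metric column: correlation undefined", call. = FALSE)
    }
    stats::cor(a, b, method = "pearson")
  })
  data.frame(metric_a = pairs[1, ], metric_b = pairs[2, ],
             pearson_r = as.numeric(res), stringsAsFactors = FALSE)
}

#' Published leaderboard of the RADCURE prognostic modelling challenge
#'
#' The 12 crowd-sourced submissions with their test-set AUROC, average
#' precision and C-index point estimates (95% bootstrap CI bounds included),
#' ranked by AUROC with AP as tie-break. Shipped as a plain-text table under
#' `inst/extdata/` and used for metric-agreement analyses.
#'
#' @return Data frame with columns `rank`, `description`, `auroc`,
#'   `auroc_lo`, `auroc_hi`, `ap`, `ap_lo`, `ap_hi`, `c_index`, `c_index_lo`,
#'   `c_index_hi`.
#' @export
challenge_leaderboard <- function() {
  path <- system.file("extdata", "radcure_challenge_leaderboard.csv",
                      package = "hncbench", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
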