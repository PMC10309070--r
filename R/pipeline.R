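# End-to-end challenge orchestration: simulate -> split by date -> encode ->
# train roster models on the training split only -> freeze predictions ->
# blind-evaluate on the held-out test split -> rank -> external validation on
# covariate-shifted cohorts.

#' Default external-cohort shift presets
#'
#' Three qualitative covariate-shift scenarios, emulating the kinds of
#' population differences seen between institutions: a disease-site mix
#' shift (oropharynx/larynx-dominated referral pattern), a single-site
#' oropharynx cohort with higher HPV positivity, and a cohort with a
#' disproportionately high share of HPV-negative patients. Magnitudes are
#' illustrative defaults, not estimates of any real cohort; the ground-truth
#' outcome model is shared, so only the covariate mix (and through it the
#' event prevalence) shifts.
#'
#' @return Named list of shift specifications for [apply_shift()].
#' @export
default_shift_presets <- function() {
  list(
    site_shift = list(
      disease_site = list(probs = c(0.55, 0.35, 0.02, 0.04, 0.04))
    ),
    oropharynx_shift = list(
      disease_site = list(probs = c(1, 0, 0, 0, 0)),
      hpv_status = list(probs = c(0.65, 0.20, 0.15))
    ),
    hpv_negative_shift = list(
      hpv_status = list(probs = c(0.15, 0.70, 0.15))
    )
  )
}

#' Challenge configuration
#'
#' Bundles the cohort simulation settings, external-shift presets, the model
#' roster and the evaluation settings of one full benchmark run.
#'
#' @param cohort A [cohort_config()].
#' @param shift_configs Named list of shift presets for external validation.
#' @param model_roster Models to train; any subset of `deep_mtlr`,
#'   `linear_mtlr`, `logistic_emr`, `cox_emr`, `volume_only`,
#'   `clinical_baseline`, `mrmr_feature_model`.
#' @param train_fraction Share of patients (earliest diagnoses) in training.
#' @param horizon_months Binarisation horizon; must equal the last boundary
#'   of `grid`.
#' @param grid [time_grid()] for the MTLR models.
#' @param n_boot Bootstrap replicates for CIs and model comparisons.
#' @param n_perm Permutations for the better-than-random tests.
#' @param n_synth_features,volume_coupling,noise_sd Synthetic feature block
#'   standing in for engineered image features (used by
#'   `mrmr_feature_model`).
#' @param hidden_width ELU encoder width of the deep MTLR.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Object of class `challenge_config`.
#' @export
challenge_config <- function(cohort = cohort_config(),
                             shift_configs = default_shift_presets(),
                             model_roster = c("deep_mtlr", "linear_mtlr",
                                              "logistic_emr", "cox_emr",
                                              "volume_only",
                                              "clinical_baseline",
                                              "mrmr_feature_model"),
                             train_fraction = 0.706,
                             horizon_months = 24,
                             grid = time_grid(24),
                             n_boot = 500, n_perm = 500,
                             n_synth_features = 50,
                             volume_coupling = 0.6, noise_sd = 1,
                             hidden_width = 32,
                             seed = 1L) {
  if (!length(model_roster)) stop("model roster is empty", call. = FALSE)
  unknown <- setdiff(model_roster,
                     c("deep_mtlr", "linear_mtlr", "logistic_emr", "cox_emr",
                       "volume_only", "clinical_baseline",
                       "mrmr_feature_model"))
  if (length(unknown)) {
    stop("unknown roster models: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (abs(horizon_months - max(grid)) > 1e-9) {
    stop("`horizon_months` must equal the final grid boundary so the 2-year ",
         "event probability and the binary label share a horizon",
         call. = FALSE)
  }
  structure(list(cohort = cohort, shift_configs = shift_configs,
                 model_roster = model_roster,
                 train_fraction = train_fraction,
                 horizon_months = horizon_months, grid = grid,
                 n_boot = n_boot, n_perm = n_perm,
                 n_synth_features = n_synth_features,
                 volume_coupling = volume_coupling, noise_sd = noise_sd,
                 hidden_width = hidden_width,
                 seed = as.integer(seed)),
            class = "challenge_config")
}

EMR_VARIABLES <- c("age", "sex", "t_stage", "n_stage", "overall_stage",
                   "disease_site", "performance_status", "hpv_status",
                   "dose_gy", "chemotherapy")
CLINICAL_VARIABLES <- c("age", "sex", "t_stage", "n_stage", "hpv_status")

# fixed seed offsets so every stage has its own reproducible stream
stage_seed <- function(seed, stage) {
  offsets <- c(features = 101L, deep = 202L, tune = 303L, boot = 404L,
               perm = 505L, external = 606L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Train the challenge model roster on the training split
#'
#' Fits every roster model on the training cohort only. Encoding schemas are
#' fitted on the training split and frozen into the returned object, so
#' external cohorts are encoded with training-set statistics. Individual
#' model failures are caught and recorded; the rest of the roster proceeds.
#'
#' Logistic, Cox and mRMR baselines tune their ridge strength (and the mRMR
#' feature count) by stratified 5-fold grid-search CV on the training split;
#' the MTLR models use the package defaults.
#'
#' @param train_cohort Training cohort (with outcomes).
#' @param train_features Synthetic feature block rows for the training
#'   patients (`feature_matrix`), or `NULL` to skip `mrmr_feature_model`.
#' @param config A [challenge_config()].
#' @return Object of class `trained_models`: per-model fits, frozen schemas,
#'   failures.
#' @export
train_challenge_models <- function(train_cohort, train_features, config) {
  y_train <- binarize_outcome(train_cohort, config$horizon_months)
  surv_train <- list(time_months = train_cohort$time_months,
                     event = train_cohort$event)

  schema_full <- fit_schema(train_cohort,
                            c(EMR_VARIABLES, "volume_cc"))
  schema_emr <- fit_schema(train_cohort, EMR_VARIABLES)
  schema_clin <- fit_schema(train_cohort, CLINICAL_VARIABLES)

  X_full <- encode(train_cohort, schema_full)
  X_emr <- encode(train_cohort, schema_emr)
  X_clin <- encode(train_cohort, schema_clin)

  models <- list()
  failures <- list()
  add_model <- function(name, fit_expr) {
    res <- tryCatch(fit_expr(), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[name]] <<- conditionMessage(res)
    } else {
      models[[name]] <<- res
    }
  }

  l2_grid <- data.frame(l2_strength = c(0.1, 1, 10, 100))
  tune_linear <- function(X, fitter) {
    tuned <- tune_by_grid_cv(
      X, y_train, l2_grid,
      fit_fn = function(Xt, yt, params) fitter(Xt, yt, params$l2_strength),
      predict_fn = predict_linear_model,
      seed = stage_seed(config$seed, "tune"))
    tuned$best$l2_strength
  }

  roster <- config$model_roster
  if ("deep_mtlr" %in% roster) {
    add_model("deep_mtlr", function() {
      fit_mtlr(X_full, surv_train$time_months, surv_train$event,
               grid = config$grid, hidden_width = config$hidden_width,
               seed = stage_seed(config$seed, "deep"))
    })
  }
  if ("linear_mtlr" %in% roster) {
    add_model("linear_mtlr", function() {
      fit_mtlr(X_full, surv_train$time_months, surv_train$event,
               grid = config$grid)
    })
  }
  if ("logistic_emr" %in% roster) {
    add_model("logistic_emr", function() {
      fit_logistic(X_emr, y_train, tune_linear(X_emr, fit_logistic))
    })
  }
  if ("cox_emr" %in% roster) {
    add_model("cox_emr", function() {
      fit_cox(X_emr, surv_train$time_months, surv_train$event,
              l2_strength = 1)
    })
  }
  if ("volume_only" %in% roster) {
    add_model("volume_only", function() {
      volume_only_model(train_cohort$volume_cc, y_train)
    })
  }
  if ("clinical_baseline" %in% roster) {
    add_model("clinical_baseline", function() {
      fit_logistic(X_clin, y_train, tune_linear(X_clin, fit_logistic))
    })
  }
  if ("mrmr_feature_model" %in% roster && !is.null(train_features)) {
    add_model("mrmr_feature_model", function() {
      p <- ncol(train_features$values)
      grid <- expand.grid(m = unique(pmin(c(5, 10, 20), p)),
                          l2_strength = c(0.1, 1, 10))
      tuned <- tune_by_grid_cv(
        train_features, y_train, grid,
        fit_fn = function(Xt, yt, params) {
          sel <- mrmr_select(Xt, yt, params$m)
          fit <- fit_logistic(Xt[, sel$selected_indices, drop = FALSE], yt,
                              params$l2_strength)
          fit$selection <- sel
          fit
        },
        predict_fn = function(model, Xv) {
          predict_linear_model(
            model, Xv[, model$selection$selected_indices, drop = FALSE])
        },
        seed = stage_seed(config$seed, "tune"))
      sel <- mrmr_select(train_features, y_train, tuned$best$m)
      fit <- fit_logistic(
        train_features$values[, sel$selected_indices, drop = FALSE],
        y_train, tuned$best$l2_strength)
      fit$selection <- sel
      fit$tuned <- tuned$best
      fit
    })
  }

  structure(list(models = models, failures = failures,
                 schema_full = schema_full, schema_emr = schema_emr,
                 schema_clinical = schema_clin,
                 config = config),
            class = "trained_models")
}

#' @export
print.trained_models <- function(x, ...) {
  cat("<trained_models> ", length(x$models), " fitted (",
      paste(names(x$models), collapse = ", "), ")\n", sep = "")
  if (length(x$failures)) {
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict with all trained models on a new cohort
#'
#' Applies the frozen encoding schemas and models to a cohort's covariates.
#' Outcome columns are dropped before prediction, so no model can see test
#' outcomes. Each model yields a binary score (2-year event probability or a
#' rank-equivalent proxy) and a lifetime risk score. The result is unfrozen;
#' call [freeze_predictions()] before evaluation.
#'
#' @param trained A `trained_models` object.
#' @param cohort Cohort to predict for (outcomes ignored).
#' @param features Synthetic feature block rows for these patients, or
#'   `NULL`.
#' @return Object of class `challenge_predictions`: per-model lists with
#'   `binary_score`, `risk_score` and (for MTLR models) the
#'   `prediction_set`.
#' @export
predict_challenge_models <- function(trained, cohort, features = NULL) {
  covars <- cohort[, setdiff(names(cohort), c("time_months", "event")),
                   drop = FALSE]
  X_full <- encode(covars, trained$schema_full)
  X_emr <- encode(covars, trained$schema_emr)
  X_clin <- encode(covars, trained$schema_clinical)
  preds <- list()
  for (nm in names(trained$models)) {
    model <- trained$models[[nm]]
    preds[[nm]] <- switch(
      nm,
      deep_mtlr = ,
      linear_mtlr = {
        ps <- predict_mtlr(model, X_full)
        list(binary_score = ps$event_prob_2y, risk_score = ps$risk_score,
             prediction_set = ps)
      },
      logistic_emr = {
        p <- predict_linear_model(model, X_emr)
        list(binary_score = p, risk_score = p)
      },
      cox_emr = {
        r <- predict_linear_model(model, X_emr)
        list(binary_score = r, risk_score = r)
      },
      volume_only = {
        p <- predict_volume_only(model, covars$volume_cc)
        list(binary_score = p, risk_score = p)
      },
      clinical_baseline = {
        p <- predict_linear_model(model, X_clin)
        list(binary_score = p, risk_score = p)
      },
      mrmr_feature_model = {
        sel <- model$selection$selected_indices
        p <- predict_linear_model(
          model, features$values[, sel, drop = FALSE])
        list(binary_score = p, risk_score = p)
      }
    )
  }
  structure(list(predictions = preds, n = nrow(cohort), frozen = FALSE),
            class = "challenge_predictions")
}

#' Freeze a prediction set for blind evaluation
#'
#' Marks the predictions as final. [evaluate_challenge()] refuses unfrozen
#' predictions, enforcing the challenge discipline that prediction files are
#' fixed before any test outcome is consulted.
#'
#' @param predictions A `challenge_predictions` object.
#' @return The same object with `frozen = TRUE`.
#' @export
freeze_predictions <- function(predictions) {
  stopifnot(inherits(predictions, "challenge_predictions"))
  predictions$frozen <- TRUE
  predictions
}

#' Blind-evaluate frozen predictions against test outcomes
#'
#' Computes AUROC, AP (on the binary scores) and the C-index (on the risk
#' scores) with stratified bootstrap CIs, a better-than-random permutation
#' p-value per model, ranks models by AUROC with AP as tie-break, and flags
#' models whose AUROC is significantly below the best model's at BH-FDR 5%
#' (shared-replicate paired bootstrap t-test).
#'
#' @param predictions A frozen `challenge_predictions`.
#' @param test_cohort Test cohort with outcomes.
#' @param config A [challenge_config()].
#' @return Object of class `evaluation_report`: `ranking` (data frame sorted
#'   by rank), `comparisons`, `n_test`.
#' @export
evaluate_challenge <- function(predictions, test_cohort, config) {
  stopifnot(inherits(predictions, "challenge_predictions"))
  if (!isTRUE(predictions$frozen)) {
    stop("predictions must be frozen with `freeze_predictions()` before ",
         "test outcomes are evaluated", call. = FALSE)
  }
  if (predictions$n != nrow(test_cohort)) {
    stop("prediction/patient count mismatch", call. = FALSE)
  }
  y <- binarize_outcome(test_cohort, config$horizon_months)
  surv <- list(time_months = test_cohort$time_months,
               event = test_cohort$event)
  boot_seed <- stage_seed(config$seed, "boot")
  perm_seed <- stage_seed(config$seed, "perm")

  rows <- lapply(names(predictions$predictions), function(nm) {
    pr <- predictions$predictions[[nm]]
    a <- stratified_bootstrap_ci(auroc, pr$binary_score, y,
                                 n_boot = config$n_boot, seed = boot_seed)
    ap <- stratified_bootstrap_ci(average_precision, pr$binary_score, y,
                                  n_boot = config$n_boot, seed = boot_seed)
    ci <- stratified_bootstrap_ci(c_index, pr$risk_score, surv,
                                  n_boot = config$n_boot, seed = boot_seed)
    pv <- permutation_test(auroc, pr$binary_score, y,
                           n_perm = config$n_perm, seed = perm_seed)
    data.frame(model = nm,
               auroc = a$estimate, auroc_lo = a$ci_low, auroc_hi = a$ci_high,
               ap = ap$estimate, ap_lo = ap$ci_low, ap_hi = ap$ci_high,
               c_index = ci$estimate, c_index_lo = ci$ci_low,
               c_index_hi = ci$ci_high,
               perm_p = pv$p_value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$auroc, -tab$ap), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  comparisons <- NULL
  if (nrow(tab) > 1) {
    best <- tab$model[1]
    others <- tab$model[-1]
    pvals <- vapply(others, function(nm) {
      compare_models(predictions$predictions[[best]]$binary_score,
                     predictions$predictions[[nm]]$binary_score,
                     y, n_boot = config$n_boot, seed = boot_seed)$p_value
    }, numeric(1))
    adj <- fdr_adjust(pvals, 0.05)
    comparisons <- data.frame(model = others, p_vs_best = unname(pvals),
                              p_adjusted = adj$adjusted,
                              best_significantly_better = adj$rejected,
                              stringsAsFactors = FALSE)
    tab$best_significantly_better <-
      c(NA, adj$rejected)[match(tab$model, c(best, others))]
  }
  structure(list(ranking = tab[, c("rank", setdiff(names(tab), "rank"))],
                 comparisons = comparisons, n_test = nrow(test_cohort)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", nrow(x$ranking), " models, n_test = ",
      x$n_test, "\n", sep = "")
  print(x$ranking[, c("rank", "model", "auroc", "ap", "c_index")],
        digits = 3)
  invisible(x)
}

#' Run the full challenge
#'
#' Simulates the cohort, splits it by diagnosis date, generates the synthetic
#' feature block, trains every roster model on the training split, freezes
#' the test predictions and blind-evaluates them. Deterministic for a fixed
#' configuration seed.
#'
#' @param config A [challenge_config()].
#' @return List with `report` (the [evaluate_challenge()] output), `trained`,
#'   `predictions`, `cohort`, `split`, `features`.
#' @export
run_challenge <- function(config) {
  stopifnot(inherits(config, "challenge_config"))
  cohort <- generate_cohort(config$cohort)
  features <- generate_feature_block(cohort, config$n_synth_features,
                                     config$volume_coupling, config$noise_sd,
                                     seed = stage_seed(config$seed,
                                                       "features"))
  split <- split_by_date(cohort, config$train_fraction)
  row_of <- match(split$train$patient_id, cohort$patient_id)
  feats_train <- new_feature_matrix(
    features$values[row_of, , drop = FALSE])
  row_of_test <- match(split$test$patient_id, cohort$patient_id)
  feats_test <- new_feature_matrix(
    features$values[row_of_test, , drop = FALSE])

  trained <- train_challenge_models(split$train, feats_train, config)
  predictions <- predict_challenge_models(trained, split$test, feats_test)
  predictions <- freeze_predictions(predictions)
  report <- evaluate_challenge(predictions, split$test, config)
  list(report = report, trained = trained, predictions = predictions,
       cohort = cohort, split = split,
       features = list(train = feats_train, test = feats_test))
}

#' External validation on covariate-shifted cohorts
#'
#' For every shift preset, generates an external cohort from the shifted
#' configuration (same ground-truth coefficients), applies the frozen
#' schemas and models, blind-evaluates, and tests the covariate shift
#' between the internal test set and the external cohort.
#'
#' @param trained A `trained_models` object.
#' @param internal_test The internal test cohort (for the shift tests).
#' @param config A [challenge_config()]; its `shift_configs` are used unless
#'   `shift_configs` is supplied.
#' @param shift_configs Optional named list overriding the presets.
#' @param n_external Patients per external cohort (default: the internal
#'   test-set size).
#' @return Named list per external cohort: `report`, `shift_test`, `cohort`.
#' @export
run_external_validation <- function(trained, internal_test, config,
                                    shift_configs = NULL,
                                    n_external = NULL) {
  shifts <- if (is.null(shift_configs)) config$shift_configs else
    shift_configs
  if (!length(shifts)) return(list())
  n_ext <- if (is.null(n_external)) nrow(internal_test) else n_external
  out <- list()
  i <- 0L
  for (nm in names(shifts)) {
    i <- i + 1L
    ext_cfg <- apply_shift(config$cohort, shifts[[nm]],
                           seed = stage_seed(config$seed, "external") + i,
                           cohort_label = nm)
    ext_cfg$n_patients <- as.integer(n_ext)
    ext_cohort <- generate_cohort(ext_cfg)
    ext_feats <- generate_feature_block(
      ext_cohort, config$n_synth_features, config$volume_coupling,
      config$noise_sd, seed = stage_seed(config$seed, "features") + i)
    preds <- freeze_predictions(
      predict_challenge_models(trained, ext_cohort, ext_feats))
    report <- evaluate_challenge(preds, ext_cohort, config)
    shift_test <- cohort_shift_test(internal_test, ext_cohort)
    out[[nm]] <- list(report = report, shift_test = shift_test,
                      cohort = ext_cohort, predictions = preds)
  }
  out
}

# small polynomial-rolling digest for labelling outputs with their
# configuration (not cryptographic; collisions only mislabel a run)
config_digest <- function(config) {
  s <- jsonlite::serializeJSON(config, digits = 10)
  h <- 5381
  for (v in utf8ToInt(as.character(s))) {
    h <- (h * 33 + v) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a challenge run to machine- and human-readable files
#'
#' Produces the ranking table (CSV), a volume-dependence table (CSV), a
#' risk-stratification summary for the top model (JSON), per-external-cohort
#' rankings and shift tests (CSV), and a run manifest with the seed and a
#' configuration digest (JSON).
#'
#' @param results Output of [run_challenge()].
#' @param external Optional output of [run_external_validation()].
#' @param outdir Output directory (created if needed).
#' @param config The [challenge_config()] used.
#' @return Invisibly, the vector of files written.
#' @export
report_challenge <- function(results, external = NULL, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(results$report$ranking, "ranking.csv")
  if (!is.null(results$report$comparisons)) {
    wr(results$report$comparisons, "comparisons_vs_best.csv")
  }

  test <- results$split$test
  binary_preds <- lapply(results$predictions$predictions,
                         function(p) p$binary_score)
  perf <- vapply(results$report$ranking$model, function(m) {
    results$report$ranking$auroc[results$report$ranking$model == m]
  }, numeric(1))
  voldep <- volume_dependence(binary_preds, test$volume_cc, perf)
  wr(voldep, "volume_dependence.csv")

  top <- results$report$ranking$model[1]
  strat <- tryCatch(
    km_stratify(binary_preds[[top]], test$time_months, test$event),
    error = function(e) NULL)
  manifest <- list(seed = config$seed, config_digest = config_digest(config),
                   n_train = nrow(results$split$train),
                   n_test = nrow(test),
                   models = names(results$predictions$predictions),
                   failures = results$trained$failures,
                   top_model = top,
                   stratification = if (is.null(strat)) NULL else
                     list(hazard_ratio = strat$hazard_ratio,
                          hr_ci = strat$hr_ci,
                          logrank_p = strat$logrank_p))
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, manifest_path)

  for (nm in names(external)) {
    wr(external[[nm]]$report$ranking,
       paste0("external_", nm, "_ranking.csv"))
    wr(external[[nm]]$shift_test, paste0("external_", nm, "_shift.csv"))
  }
  invisible(files)
}
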