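# Benchmark models: L2-penalised logistic regression (binary endpoint), Cox
# proportional hazards (survival endpoint), volume-only variants, mRMR
# feature selection and the shared 5-fold grid-search tuning protocol.

#' Fit an L2-penalised logistic regression
#'
#' Maximises the Bernoulli log-likelihood minus
#' \eqn{(l2/2)\,\lVert\beta\rVert^2} (intercept unpenalised), via glmnet with
#' a ridge-only penalty. `l2_strength` is on the summed-log-likelihood scale.
#'
#' @param X Feature matrix (`feature_matrix` or numeric matrix).
#' @param y 0/1 labels; both classes must be present.
#' @param l2_strength Nonnegative ridge strength.
#' @return A `linear_model` with `model_kind = "binary_logistic"`.
#' @export
fit_logistic <- function(X, y, l2_strength = 1) {
  X <- as_values(X)
  y <- check_binary(y)
  if (length(unique(y)) < 2) {
    stop("degenerate data: only one class present", call. = FALSE)
  }
  if (l2_strength < 0) stop("`l2_strength` must be >= 0", call. = FALSE)
  n <- nrow(X)
  if (ncol(X) == 1) X_fit <- cbind(X, `.pad` = 0) else X_fit <- X
  fit <- glmnet::glmnet(X_fit, y, family = "binomial", alpha = 0,
                        lambda = max(l2_strength, 1e-8) / n,
                        standardize = FALSE, thresh = 1e-12)
  beta <- as.numeric(fit$beta)[seq_len(ncol(X))]
  names(beta) <- colnames(X)
  new_linear_model(beta, intercept = as.numeric(fit$a0),
                   l2_strength = l2_strength,
                   model_kind = "binary_logistic")
}

#' Fit an L2-penalised Cox proportional hazards model
#'
#' Maximises the Breslow partial log-likelihood minus
#' \eqn{(l2/2)\,\lVert\beta\rVert^2}, via glmnet's Cox family. The risk score
#' is the linear predictor \eqn{x \cdot \beta}.
#'
#' @param X Feature matrix.
#' @param time_months Positive follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @param l2_strength Nonnegative ridge strength.
#' @return A `linear_model` with `model_kind = "cox_ph"`.
#' @export
fit_cox <- function(X, time_months, event, l2_strength = 1) {
  X <- as_values(X)
  event <- as.integer(event)
  if (sum(event) == 0) {
    stop("degenerate data: no events", call. = FALSE)
  }
  if (l2_strength < 0) stop("`l2_strength` must be >= 0", call. = FALSE)
  n <- nrow(X)
  if (ncol(X) == 1) X_fit <- cbind(X, `.pad` = 0) else X_fit <- X
  fit <- glmnet::glmnet(X_fit, survival::Surv(time_months, event),
                        family = "cox", alpha = 0,
                        lambda = max(l2_strength, 1e-8) / n,
                        standardize = FALSE, thresh = 1e-12)
  beta <- as.numeric(fit$beta)[seq_len(ncol(X))]
  names(beta) <- colnames(X)
  new_linear_model(beta, intercept = 0, l2_strength = l2_strength,
                   model_kind = "cox_ph")
}

new_linear_model <- function(coefficients, intercept, l2_strength,
                             model_kind) {
  structure(list(coefficients = coefficients, intercept = intercept,
                 l2_strength = l2_strength, model_kind = model_kind),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model> ", x$model_kind, ", ", length(x$coefficients),
      " coefficients, l2 = ", x$l2_strength, "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted linear baseline
#'
#' Logistic models return event probabilities; Cox models return the linear
#' predictor as the risk score.
#'
#' @param model A `linear_model`.
#' @param X Feature matrix.
#' @return Numeric prediction vector.
#' @export
predict_linear_model <- function(model, X) {
  X <- as_values(X)
  lp <- as.numeric(X %*% model$coefficients + model$intercept)
  if (model$model_kind == "binary_logistic") stats::plogis(lp) else lp
}

#' Breslow partial log-likelihood
#'
#' Direct evaluation of the Cox partial likelihood with Breslow tie
#' handling, used to verify fitted models against hand enumeration.
#'
#' @param beta Coefficient vector.
#' @param X Feature matrix.
#' @param time_months,event Outcomes.
#' @return Scalar partial log-likelihood.
#' @export
cox_partial_loglik <- function(beta, X, time_months, event) {
  X <- as_values(X)
  lp <- as.numeric(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk_set <- time_months >= time_months[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk_set])))
  }
  ll
}

# ---- mutual information and mRMR ---------------------------------------

# equal-frequency binning; already-discrete vectors (few unique values) pass
# through unchanged
discretize_ef <- function(x, n_bins = 8) {
  u <- unique(x)
  if (length(u) <= n_bins) return(match(x, sort(u)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Maximum-relevance minimum-redundancy feature selection
#'
#' Greedy forward selection using the difference criterion: at each step the
#' chosen feature maximises (mutual information with the outcome) minus (mean
#' mutual information with the already-selected features), all estimated on
#' equal-frequency binned features. The first pick maximises relevance alone.
#'
#' @param F Feature matrix.
#' @param y 0/1 labels.
#' @param m Number of features to select (1..n_features).
#' @param n_bins Bins for the equal-frequency discretisation.
#' @return A `selection_result`: `selected_indices` (in pick order),
#'   `selected_names`, `scores` (criterion value at each step),
#'   `relevance` (per-feature MI with the outcome).
#' @export
mrmr_select <- function(F, y, m, n_bins = 8) {
  vals <- as_values(F)
  y <- check_binary(y)
  p <- ncol(vals)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (m > p) stop("`m` exceeds the number of features", call. = FALSE)
  disc <- apply(vals, 2, discretize_ef, n_bins = n_bins)
  relevance <- apply(disc, 2, mutual_information, b = y)
  selected <- integer(0)
  scores <- numeric(0)
  red_cache <- matrix(NA_real_, p, p)
  for (step in seq_len(m)) {
    remaining <- setdiff(seq_len(p), selected)
    crit <- vapply(remaining, function(j) {
      if (!length(selected)) return(relevance[j])
      red <- vapply(selected, function(s) {
        if (is.na(red_cache[j, s])) {
          red_cache[j, s] <<- mutual_information(disc[, j], disc[, s])
          red_cache[s, j] <<- red_cache[j, s]
        }
        red_cache[j, s]
      }, numeric(1))
      relevance[j] - mean(red)
    }, numeric(1))
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
  }
  structure(list(selected_indices = selected,
                 selected_names = colnames(vals)[selected],
                 scores = scores, relevance = relevance),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected_indices),
      " features selected\n", sep = "")
  invisible(x)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    fold_id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_id
  })
}

#' Grid-search hyperparameter tuning with stratified 5-fold CV
#'
#' Evaluates every configuration in `grid` by mean validation AUROC over
#' label-stratified folds and returns the best row. Ties are broken toward
#' stronger regularisation (larger `l2_strength`) and fewer selected features
#' (smaller `m`), when those columns exist.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param grid Data frame of configurations, one row each (e.g. from
#'   [expand.grid()]).
#' @param fit_fn Function `(X_train, y_train, params_row) -> model`.
#' @param predict_fn Function `(model, X_val) -> scores`.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return List with `best` (the winning grid row), `cv_auroc` (per-row mean
#'   validation AUROC), `fold_id`.
#' @export
tune_by_grid_cv <- function(X, y, grid, fit_fn, predict_fn, folds = 5,
                            seed = 1L) {
  if (!nrow(grid)) stop("`grid` is empty", call. = FALSE)
  vals <- as_values(X)
  y <- check_binary(y)
  fold_id <- stratified_folds(y, folds, seed)
  cv_auroc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- grid[g, , drop = FALSE]
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      model <- fit_fn(vals[tr, , drop = FALSE], y[tr], params)
      auroc(predict_fn(model, vals[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best_score <- max(cv_auroc)
  cand <- which(cv_auroc >= best_score - 1e-12)
  if (length(cand) > 1) {
    ord_cols <- list()
    if ("l2_strength" %in% names(grid)) {
      ord_cols <- c(ord_cols, list(-grid$l2_strength[cand]))
    }
    if ("m" %in% names(grid)) ord_cols <- c(ord_cols, list(grid$m[cand]))
    if (length(ord_cols)) cand <- cand[do.call(order, ord_cols)]
  }
  list(best = grid[cand[1], , drop = FALSE], cv_auroc = cv_auroc,
       fold_id = fold_id)
}

#' Volume-only baseline
#'
#' Single-covariate model on standardised log tumor volume: logistic
#' regression when a binary outcome is given, Cox proportional hazards when a
#' `time_months`/`event` outcome is given.
#'
#' @param volume_cc Tumor volumes.
#' @param outcome Either a 0/1 label vector or a list/data frame with
#'   `time_months` and `event`.
#' @param l2_strength Ridge strength.
#' @return A `linear_model`; its single feature is standardised log volume
#'   (use [predict_volume_only()] or standardise identically before
#'   predicting).
#' @export
volume_only_model <- function(volume_cc, outcome, l2_strength = 1e-4) {
  x <- matrix(as.numeric(scale(log(volume_cc))), ncol = 1,
              dimnames = list(NULL, "log_volume_cc"))
  if (is.list(outcome) && !is.null(outcome$time_months)) {
    model <- fit_cox(x, outcome$time_months, outcome$event, l2_strength)
  } else {
    model <- fit_logistic(x, outcome, l2_strength)
  }
  model$volume_stats <- c(mean = mean(log(volume_cc)),
                          sd = stats::sd(log(volume_cc)))
  model
}

#' @rdname volume_only_model
#' @param model A volume-only `linear_model`.
#' @param new_volume_cc Volumes to predict for (standardised with the
#'   training statistics stored in the model).
#' @export
predict_volume_only <- function(model, new_volume_cc) {
  st <- model$volume_stats
  x <- matrix((log(new_volume_cc) - st["mean"]) / st["sd"], ncol = 1)
  predict_linear_model(model, x)
}

#' Save a selection result / tuned configuration as JSON
#'
#' @param selection A `selection_result` (or `NULL`).
#' @param config A tuned configuration row (or `NULL`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
selection_to_json <- function(selection, config, path) {
  jsonlite::write_json(
    list(selected_indices = selection$selected_indices,
         selected_names = selection$selected_names,
         scores = selection$scores,
         tuned_config = as.list(config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
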