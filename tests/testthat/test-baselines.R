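test_that("ridge logistic regression approaches the MLE as l2 -> 0", {
  set.seed(1)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, "a"] - 0.5 * X[, "b"]))
  fit <- fit_logistic(X, y, l2_strength = 1e-6)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-3)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-3)
  expect_equal(predict_linear_model(fit, X),
               unname(plogis(cbind(1, X) %*% coef(ref))[, 1]),
               tolerance = 1e-3)
})

test_that("stronger ridge shrinks logistic coefficients monotonically", {
  set.seed(2)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x", "y", "z")))
  y <- rbinom(n, 1, plogis(X[, 1]))
  norms <- vapply(c(0.1, 1, 10, 100),
                  function(l2) sqrt(sum(fit_logistic(X, y, l2)$coefficients^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  # single-feature path (internal zero-padding) works
  f1 <- fit_logistic(X[, 1, drop = FALSE], y, 1)
  expect_length(f1$coefficients, 1)
  expect_gt(f1$coefficients, 0)
  expect_error(fit_logistic(X, rep(1, n)), "one class")
})

test_that("ridge Cox model matches coxph as l2 -> 0 and fails without events", {
  set.seed(3)
  n <- 400
  X <- cbind(u = rnorm(n), v = rnorm(n))
  time <- rexp(n, 0.1 * exp(0.7 * X[, 1])) + 0.01
  event <- rbinom(n, 1, 0.8)
  fit <- fit_cox(X, time, event, l2_strength = 1e-6)
  ref <- survival::coxph(survival::Surv(time, event) ~ X,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-3)
  # risk score is the linear predictor
  expect_equal(predict_linear_model(fit, X),
               as.numeric(X %*% fit$coefficients))
  # fitted coefficients (near) maximise the Breslow partial likelihood
  ll_hat <- cox_partial_loglik(fit$coefficients, X, time, event)
  ll_perturbed <- cox_partial_loglik(fit$coefficients + c(0.1, 0), X, time,
                                     event)
  expect_gt(ll_hat, ll_perturbed)
  expect_error(fit_cox(X, time, rep(0, n)), "no events")
})

test_that("mutual information matches the definition and edge cases", {
  # independent variables: MI ~ 0; identical variables: MI = entropy
  a <- rep(c(1, 2), each = 50)
  b <- rep(c(1, 2), times = 50)
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)
  expect_equal(mutual_information(a, a), log(2), tolerance = 1e-12)
  # hand example: perfectly dependent 3-level variable
  x <- c(1, 1, 2, 2, 3, 3)
  expect_equal(mutual_information(x, x), log(3), tolerance = 1e-12)
})

test_that("mRMR ranks a relevant feature first and penalises redundancy", {
  set.seed(4)
  n <- 600
  y <- rbinom(n, 1, 0.5)
  signal <- y + rnorm(n, 0, 0.3)
  copy1 <- signal + rnorm(n, 0, 0.05)   # nearly identical to signal
  copy2 <- signal + rnorm(n, 0, 0.05)
  weak <- y + rnorm(n, 0, 2)            # weaker independent signal
  noise <- rnorm(n)
  F <- cbind(signal = signal, copy1 = copy1, copy2 = copy2, weak = weak,
             noise = noise)
  sel <- mrmr_select(F, y, m = 3)
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$selected_names[1], "signal")
  # the second pick avoids the redundant copies in favour of `weak`
  expect_equal(sel$selected_names[2], "weak")
  expect_length(sel$scores, 3)
  # relevance ordering: signal strongest, noise weakest
  expect_equal(names(which.max(sel$relevance)), "signal")
  expect_equal(names(which.min(sel$relevance)), "noise")
  expect_error(mrmr_select(F, y, m = 0), "m")
  expect_error(mrmr_select(F, y, m = 6), "exceeds")
})

test_that("grid-search CV is stratified, deterministic and tie-broken", {
  set.seed(5)
  n <- 250
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  grid <- data.frame(l2_strength = c(0.1, 1, 10))
  fit_fn <- function(Xt, yt, params) fit_logistic(Xt, yt, params$l2_strength)
  t1 <- tune_by_grid_cv(X, y, grid, fit_fn, predict_linear_model, seed = 6)
  t2 <- tune_by_grid_cv(X, y, grid, fit_fn, predict_linear_model, seed = 6)
  expect_identical(t1$cv_auroc, t2$cv_auroc)
  expect_true(t1$best$l2_strength %in% grid$l2_strength)
  # folds are label-stratified: per-fold prevalence close to overall
  prev <- mean(y)
  for (f in 1:5) {
    expect_lt(abs(mean(y[t1$fold_id == f]) - prev), 5 / sum(t1$fold_id == f))
  }
  # tie-break prefers the stronger regulariser when scores are equal
  const_fit <- function(Xt, yt, params) structure(list(), class = "cst")
  const_pred <- function(model, Xv) rep(0.5, nrow(Xv))
  tt <- tune_by_grid_cv(X, y, grid, const_fit, const_pred, seed = 6)
  expect_equal(tt$best$l2_strength, 10)
  expect_error(tune_by_grid_cv(X, y, grid[0, , drop = FALSE], fit_fn,
                               predict_linear_model), "empty")
})

test_that("volume-only baseline predicts from frozen volume statistics", {
  co <- generate_cohort(tiny_config(n = 1200, seed = 7))
  y <- binarize_outcome(co)
  m <- volume_only_model(co$volume_cc, y)
  expect_equal(m$model_kind, "binary_logistic")
  # larger volume -> higher event probability under the true model
  p_small <- predict_volume_only(m, 5)
  p_large <- predict_volume_only(m, 100)
  expect_gt(p_large, p_small)
  # predictions use stored training stats: shifting the query set alone
  # cannot change a single patient's prediction
  expect_equal(predict_volume_only(m, c(5, 500))[1], p_small)
  # Cox variant via survival outcome
  mc <- volume_only_model(co$volume_cc,
                          list(time_months = co$time_months,
                               event = co$event))
  expect_equal(mc$model_kind, "cox_ph")
})

test_that("selection results serialize to JSON with their tuned config", {
  set.seed(8)
  F <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(50, 1, 0.5)
  y[1:2] <- c(0L, 1L)
  sel <- mrmr_select(F, y, 2)
  path <- withr::local_tempfile(fileext = ".json")
  selection_to_json(sel, data.frame(m = 2, l2_strength = 1), path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$selected_indices, sel$selected_indices)
  expect_equal(obj$selected_names, sel$selected_names)
  expect_equal(obj$tuned_config$m, 2)
})
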