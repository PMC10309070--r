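rand_mtlr <- function(K, d, seed) {
  set.seed(seed)
  mtlr_model(time_grid(K), matrix(rnorm(K * d), K, d), rnorm(K))
}

test_that("sequence probabilities match exhaustive enumeration", {
  for (s in 1:20) {
    K <- sample(2:6, 1)
    d <- sample(1:4, 1)
    model <- rand_mtlr(K, d, s)
    X <- matrix(rnorm(3 * d), 3, d)
    P <- mtlr_sequence_probs(model, X)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
    for (i in 1:3) {
      expect_equal(P[i, ], mtlr_probs_enum(model$weights, model$biases,
                                           X[i, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("an all-zero model yields the uniform sequence distribution", {
  K <- 24
  model <- mtlr_model(time_grid(K), matrix(0, K, 3), rep(0, K))
  X <- matrix(rnorm(6), 2, 3)
  P <- mtlr_sequence_probs(model, X)
  expect_equal(P, matrix(1 / (K + 1), 2, K + 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  ps <- predict_mtlr(model, X)
  # S(tau_k) = (K + 1 - k)/(K + 1)
  expect_equal(ps$survival_curve[1, ], (K + 1 - seq_len(K)) / (K + 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hand-computed K = 3 example is reproduced end to end", {
  # choose weights/bias so the sequence probabilities are (.1, .2, .3, .4)
  p <- c(0.1, 0.2, 0.3, 0.4)
  s <- log(p / p[4])           # scores relative to the survive-all sequence
  b <- c(s[1] - s[2], s[2] - s[3], s[3])  # eta_k = s_k - s_{k+1}
  model <- mtlr_model(time_grid(3), matrix(0, 3, 1), b)
  x <- matrix(0, 1, 1)
  expect_equal(as.numeric(mtlr_sequence_probs(model, x)), p,
               tolerance = 1e-12)
  ps <- predict_mtlr(model, x)
  expect_equal(as.numeric(ps$survival_curve), c(0.9, 0.7, 0.4),
               tolerance = 1e-12)
  expect_equal(ps$event_prob_2y, 0.6, tolerance = 1e-12)
  expect_equal(ps$risk_score, (1 - 0.9) + (1 - 0.7) + (1 - 0.4),
               tolerance = 1e-12)
})

test_that("log-likelihood matches enumeration for events and censoring", {
  for (s in 1:10) {
    K <- sample(2:6, 1)
    d <- 2
    model <- rand_mtlr(K, d, 100 + s)
    n <- 8
    X <- matrix(rnorm(n * d), n, d)
    time <- runif(n, 0.2, K + 2)          # includes times past the grid
    event <- rbinom(n, 1, 0.5)
    # events past the grid fall in the K+1 sequence; keep them on-grid
    time[event == 1] <- pmin(time[event == 1], K - 1e-3)
    ll <- mtlr_log_likelihood(model, X, time, event)
    ll_enum <- mtlr_loglik_enum(model$weights, model$biases, X,
                                as.numeric(model$grid), time, event)
    expect_equal(ll, ll_enum, tolerance = 1e-10)
  }
})

test_that("penalty terms subtract exactly as configured", {
  K <- 4
  W <- matrix(1:8 / 4, K, 2)
  b <- rep(0.1, K)
  base <- mtlr_model(time_grid(K), W, b)
  pen <- mtlr_model(time_grid(K), W, b, lambda_smooth = 3, lambda_ridge = 2)
  X <- matrix(rnorm(10), 5, 2)
  time <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  event <- c(1, 1, 0, 1, 0)
  expected_pen <- (3 / 2) * sum((W[-1, ] - W[-K, ])^2) + (2 / 2) * sum(W^2)
  expect_equal(mtlr_log_likelihood(base, X, time, event) -
                 mtlr_log_likelihood(pen, X, time, event),
               expected_pen, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  for (s in 1:5) {
    K <- sample(2:5, 1)
    d <- sample(1:3, 1)
    model <- rand_mtlr(K, d, 200 + s)
    model$lambda_smooth <- 0.7
    model$lambda_ridge <- 0.3
    n <- 7
    set.seed(300 + s)
    X <- matrix(rnorm(n * d), n, d)
    time <- runif(n, 0.2, K + 1)
    event <- rbinom(n, 1, 0.6)
    time[event == 1] <- pmin(time[event == 1], K - 1e-3)
    g <- mtlr_log_likelihood_grad(model, X, time, event)
    h <- 1e-5
    ll_at <- function(W, b) {
      m2 <- model; m2$weights <- W; m2$biases <- b
      mtlr_log_likelihood(m2, X, time, event)
    }
    for (idx in seq_len(K * d)) {
      Wp <- model$weights; Wp[idx] <- Wp[idx] + h
      Wm <- model$weights; Wm[idx] <- Wm[idx] - h
      fd <- (ll_at(Wp, model$biases) - ll_at(Wm, model$biases)) / (2 * h)
      expect_equal(g$weights[idx], fd, tolerance = 1e-5)
    }
    for (idx in seq_len(K)) {
      bp <- model$biases; bp[idx] <- bp[idx] + h
      bm <- model$biases; bm[idx] <- bm[idx] - h
      fd <- (ll_at(model$weights, bp) - ll_at(model$weights, bm)) / (2 * h)
      expect_equal(g$biases[idx], fd, tolerance = 1e-5)
    }
  }
})

test_that("linear fits are start-independent (concave objective)", {
  set.seed(11)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3)
  time <- rexp(n, 0.2) + 0.1
  event <- rbinom(n, 1, 0.7)
  grid <- time_grid(6, by = 2)
  f0 <- fit_mtlr(X, time, event, grid, lambda_smooth = 1, lambda_ridge = 1)
  set.seed(12)
  init <- list(weights = matrix(rnorm(18, 0, 0.5), 6, 3), biases = rnorm(6))
  f1 <- fit_mtlr(X, time, event, grid, lambda_smooth = 1, lambda_ridge = 1,
                 init = init)
  expect_equal(f0$fit_metadata$objective, f1$fit_metadata$objective,
               tolerance = 1e-6)
  expect_equal(f0$weights, f1$weights, tolerance = 1e-2)
  # fitted objective beats the zero model and the true optimum condition:
  # gradient near zero at the fitted parameters
  g <- mtlr_log_likelihood_grad(
    mtlr_model(grid, f0$weights, f0$biases, lambda_smooth = 1,
               lambda_ridge = 1), X, time, event)
  expect_lt(max(abs(g$weights)), 0.05)
  expect_lt(max(abs(g$biases)), 0.05)
})

test_that("fitting recovers risk ordering on a strongly separated cohort", {
  set.seed(21)
  n <- 400
  x <- rnorm(n)
  # one covariate, strong effect: high x dies early
  time <- rexp(n, rate = 0.05 * exp(1.5 * x)) + 0.01
  event <- rep(1L, n)
  X <- matrix(x, ncol = 1)
  fit <- fit_mtlr(X, time, event, time_grid(12, by = 2), lambda_smooth = 10,
                  lambda_ridge = 0.1)
  ps <- predict_mtlr(fit, X)
  expect_gt(cor(ps$risk_score, x, method = "spearman"), 0.95)
  expect_gt(c_index(ps$risk_score, time, event), 0.75)
})

test_that("deep variant is deterministic in its seed and fits", {
  set.seed(31)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  lp <- X[, 1] - X[, 2]
  time <- rexp(n, 0.05 * exp(lp)) + 0.01
  event <- rbinom(n, 1, 0.8)
  time[event == 0] <- pmax(time[event == 0], 1)
  grid <- time_grid(8, by = 3)
  f1 <- fit_mtlr(X, time, event, grid, hidden_width = 8, epochs = 30,
                 seed = 7)
  f2 <- fit_mtlr(X, time, event, grid, hidden_width = 8, epochs = 30,
                 seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$encoder$W, f2$encoder$W)
  ps <- predict_mtlr(f1, X)
  expect_gt(c_index(ps$risk_score, time, event), 0.6)
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_mtlr(X, c(1, 2, 3, 4, -1), rep(1, 5)), "times")
  expect_error(fit_mtlr(X, rep(1, 5), rep(0, 5)), "no events")
  expect_error(time_grid(boundaries = c(2, 1)), "strictly increasing")
  model <- rand_mtlr(3, 2, 1)
  expect_error(mtlr_sequence_logits(model, matrix(0, 2, 5)),
               "does not match")
  expect_error(prediction_set(matrix(c(0.5, 0.8), 1, 2), 0.5, 1,
                              time_grid(2)),
               "non-increasing")
  expect_error(prediction_set(matrix(1.5, 1, 1), 0.5, 1, time_grid(1)),
               "\\[0, 1\\]")
})

test_that("MTLR JSON round-trip preserves predictions for both variants", {
  set.seed(41)
  lin <- rand_mtlr(5, 3, 2)
  X <- matrix(rnorm(12), 4, 3)
  path <- withr::local_tempfile(fileext = ".json")
  mtlr_to_json(lin, path)
  lin2 <- mtlr_from_json(path)
  expect_equal(mtlr_sequence_probs(lin2, X), mtlr_sequence_probs(lin, X),
               tolerance = 1e-12)

  deep <- mtlr_model(time_grid(4), matrix(rnorm(8), 4, 2), rnorm(4),
                     encoder = list(W = matrix(rnorm(6), 3, 2), c = rnorm(2)))
  Xd <- matrix(rnorm(9), 3, 3)
  mtlr_to_json(deep, path)
  deep2 <- mtlr_from_json(path)
  expect_equal(predict_mtlr(deep2, Xd)$risk_score,
               predict_mtlr(deep, Xd)$risk_score, tolerance = 1e-12)
})
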