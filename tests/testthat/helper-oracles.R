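# Independent oracles used across the suite. These deliberately use naive
# enumeration / direct definitions, not the package's vectorised code paths.

# AUROC by exhaustive pair counting
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# average precision by stepping through every distinct threshold
ap_threshold_steps <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  r_prev <- 0
  ap <- 0
  n_pos <- sum(labels == 1)
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# Harrell C by exhaustive pair enumeration
cindex_pairs <- function(risk, time, event) {
  n <- length(risk)
  num <- 0
  den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# MTLR sequence probabilities by explicit enumeration of the K + 1 monotone
# death sequences
mtlr_probs_enum <- function(W, b, x) {
  K <- nrow(W)
  eta <- as.numeric(W %*% x + b)
  scores <- c(vapply(seq_len(K), function(k) sum(eta[k:K]), numeric(1)), 0)
  exp(scores) / sum(exp(scores))
}

# MTLR log-likelihood by enumeration (no penalty)
mtlr_loglik_enum <- function(W, b, X, grid, time, event) {
  K <- nrow(W)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    p <- mtlr_probs_enum(W, b, X[i, ])
    k <- which(time[i] <= grid)
    k <- if (length(k)) min(k) else K + 1
    if (event[i] == 1) {
      ll <- ll + log(p[k])
    } else {
      j <- min(k, K)
      ll <- ll + log(sum(p[(j + 1):(K + 1)]))
    }
  }
  ll
}

# Benjamini-Hochberg step-up from the definition
bh_reject_direct <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= q * seq_len(m) / m)))
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

# small cohort configuration used by several tests
tiny_config <- function(n = 400, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}
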