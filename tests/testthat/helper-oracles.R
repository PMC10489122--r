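# Independent brute-force oracles used to check the package implementations.

# OLS via explicit normal equations (no lm, no qr)
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * pt(-abs(tval), df), df = df)
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

bonferroni_oracle <- function(p) pmin(1, p * length(p))

# Classification metrics recomputed by direct counting over label vectors
metric_oracle <- function(predicted, actual) {
  tp <- sum(predicted == 1 & actual == 1)
  fn <- sum(predicted == 0 & actual == 1)
  tn <- sum(predicted == 0 & actual == 0)
  fp <- sum(predicted == 1 & actual == 0)
  safe <- function(a, b) if (b == 0) 0 else a / b
  ppv <- safe(tp, tp + fp)
  sens <- safe(tp, tp + fn)
  c(accuracy = safe(tp + tn, tp + fn + tn + fp),
    sensitivity = sens,
    specificity = safe(tn, tn + fp),
    ppv = ppv,
    npv = safe(tn, tn + fn),
    f_score = safe(2 * ppv * sens, ppv + sens))
}

# Intra-cluster distance recomputed with explicit loops
intra_distance_oracle <- function(tensor, cluster, centroids) {
  n <- dim(tensor)[1]
  K <- nrow(centroids)
  out <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      members <- names(cluster)[cluster == k]
      d <- vapply(members, function(r) {
        sqrt(sum((tensor[i, r, ] - centroids[k, ])^2))
      }, numeric(1))
      out[i, k] <- mean(d)
    }
  }
  out
}

default_covars <- function(cohort) cohort[c("age", "sex", "education")]

# A small null configuration: no genotype effects anywhere
null_config <- function(seed) {
  effect_config(main_effect_apoe = rep(0, 5), main_effect_mapt = rep(0, 5),
                interaction_effect = rep(0, 5), seed = seed)
}
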