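# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. seed = NULL uses the current
# stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Fixed-precision rounding matching how classification tables are typically
#' printed (0.625 -> 0.63 at 2 digits), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.625, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Batched ordinary least squares: fit y ~ X for every column of Y with one
# decomposition. Returns per-column estimates, SEs, t and two-sided p —
# for every coefficient, or only for coefficient `coef` (vectors) when the
# caller needs a single term (screening hot path). Columns of Y with zero
# residual variance get t = NA and are flagged degenerate.
batch_lm <- function(X, Y, coef = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y row mismatch")
  if (n <= p) stop("need more observations (", n, ") than predictors (", p, ")")
  # normal equations via Cholesky: the designs here are small (<= 7 columns)
  # and well-conditioned, and this is several times faster than qr() when Y
  # has hundreds of columns
  xtx <- crossprod(X)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch)) stop("design matrix is rank deficient")
  xty <- crossprod(X, Y)
  xtx_inv <- chol2inv(ch)
  coefs <- xtx_inv %*% xty           # p x m
  df <- n - p
  yty <- .colSums(Y * Y, n, ncol(Y))
  rss <- pmax(yty - .colSums(coefs * xty, p, ncol(Y)), 0)
  sigma2 <- rss / df
  degenerate <- sigma2 < 1e-24 * pmax(1, yty / n)
  if (is.null(coef)) {
    se <- sqrt(outer(diag(xtx_inv), sigma2))  # p x m
    tval <- coefs / se
    tval[, degenerate] <- NA_real_
    pval <- 2 * stats::pt(-abs(tval), df)
    est <- coefs
  } else {
    se <- sqrt(xtx_inv[coef, coef] * sigma2)
    tval <- coefs[coef, ] / se
    tval[degenerate] <- NA_real_
    pval <- 2 * stats::pt(-abs(tval), df)
    est <- coefs[coef, ]
  }
  list(estimate = est, se = se, t = tval, p = pval, df = df,
       sigma2 = sigma2, degenerate = degenerate)
}

# Mann-Whitney rank AUC of decision values for binary labels (1 = positive).
# Ties receive midranks, so a constant score gives AUC 0.5.
rank_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite")
  invisible(x)
}
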