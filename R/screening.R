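#' Covariate-adjusted group p-value for a single feature
#'
#' Two-sided p-value for the group coefficient in the linear model
#' `feature ~ group + age + sex + education` (ordinary least squares with
#' identity link; genotype coded 0/1). This is the per-feature screen applied
#' to the training split inside each cross-validation fold.
#'
#' @param feature numeric vector.
#' @param group binary vector (0/1) with both classes present.
#' @param covars data.frame or matrix with columns `age`, `sex`, `education`.
#' @return two-sided p-value for the group term.
#' @examples
#' coh <- generate_cohort(c(20, 20, 0, 0), seed = 1)
#' X <- generate_features(coh, effect_config(seed = 2))
#' glm_group_pvalue(X[, 1], coh$apoe_pos, coh[c("age", "sex", "education")])
#' @export
glm_group_pvalue <- function(feature, group, covars) {
  as.numeric(screen_pvalues(matrix(feature, ncol = 1), group, covars))
}

# Batched screen: p-value of the group term for every column of Y.
# covars may be a data.frame or a numeric matrix with the three columns.
screen_pvalues <- function(Y, group, covars) {
  if (!all(c("age", "sex", "education") %in% colnames(covars))) {
    stop("covars must contain age, sex and education")
  }
  if (length(unique(group)) < 2L) stop("group must contain both classes")
  X <- cbind(1, as.numeric(group), covars[, "age"], covars[, "sex"],
             covars[, "education"])
  batch_lm(X, Y, coef = 2L)$p
}

#' Leakage-guarded feature selection and train-statistics normalization
#'
#' Screens every feature on the training split only (covariate-adjusted
#' group GLM, keep if p < `alpha`), then z-scores both splits with the
#' training means and standard deviations of the kept features. Nothing is
#' computed from `apply_to` rows, so held-out labels cannot influence either
#' the keep mask or the normalization constants. Kept features whose training
#' standard deviation is zero are dropped with a warning.
#'
#' @param train numeric feature matrix (training rows).
#' @param labels binary training labels (0/1).
#' @param covars training covariates (`age`, `sex`, `education`).
#' @param apply_to feature matrix sharing `train`'s columns (e.g. the
#'   held-out fold); may be `NULL`.
#' @param alpha keep threshold on the screening p-value (`alpha = 1` keeps
#'   everything).
#' @return list with:
#'   \describe{
#'   \item{selection}{data.frame `feature`, `p`, `kept`, `train_mean`,
#'     `train_sd` (the per-fold selection report).}
#'   \item{train}{normalized training matrix restricted to kept features.}
#'   \item{apply_to}{normalized `apply_to` matrix on the same features.}
#'   }
#' @export
select_and_normalize <- function(train, labels, covars, apply_to = NULL,
                                 alpha = 0.05) {
  train <- as.matrix(train)
  if (!is.null(apply_to)) {
    apply_to <- as.matrix(apply_to)
    if (!identical(colnames(train), colnames(apply_to))) {
      stop("train and apply_to must share feature columns")
    }
  }
  p <- screen_pvalues(train, labels, covars)
  n <- nrow(train)
  mu <- colMeans(train)
  s <- sqrt(pmax(colSums(train^2) - n * mu^2, 0) / (n - 1))
  # NA p (zero residual variance, e.g. a constant feature) cannot pass the
  # screen on evidence; such features surface through the zero-variance drop
  kept <- is.na(p) | p < alpha
  zero_var <- kept & s == 0
  if (any(zero_var)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(train)[zero_var], collapse = ", "))
    kept <- kept & !zero_var
  }
  selection <- structure(list(feature = colnames(train),
                              p = unname(p), kept = unname(kept),
                              train_mean = unname(mu), train_sd = unname(s)),
                         class = "data.frame",
                         row.names = seq_len(ncol(train)))
  norm <- function(M) {
    M <- M[, kept, drop = FALSE]
    sweep(sweep(M, 2, mu[kept]), 2, s[kept], `/`)
  }
  list(selection = selection,
       train = norm(train),
       apply_to = if (is.null(apply_to)) NULL else norm(apply_to))
}
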