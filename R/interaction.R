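#' Mass-univariate genotype scan over morphometric features
#'
#' Per-feature general linear model comparing carriers and non-carriers while
#' controlling for age, sex and education; volume-type features (canonical
#' name ending `_volume`) are additionally adjusted for total intracranial
#' volume. Benjamini-Hochberg false-discovery-rate correction is applied
#' across all tested features. Constant features are skipped with a warning.
#'
#' @param features numeric matrix with canonical feature names.
#' @param genotype binary carrier flag (0/1).
#' @param covars data.frame with `age`, `sex`, `education`.
#' @param tiv total intracranial volume, required if volume features are
#'   present.
#' @param alpha rejection threshold applied to the adjusted p-values.
#' @return data.frame (one row per tested feature): `feature`, `estimate`,
#'   `t`, `p`, `p_adj` (BH), `reject`; attribute `skipped` lists constant
#'   features.
#' @export
univariate_scan <- function(features, genotype, covars, tiv = NULL,
                            alpha = 0.05) {
  features <- as.matrix(features)
  covars <- as.data.frame(covars)
  if (length(unique(genotype)) < 2L) stop("genotype must have both classes")
  const <- apply(features, 2, function(x) stats::sd(x) == 0)
  skipped <- colnames(features)[const]
  if (any(const)) {
    warning("skipping constant feature(s): ", paste(skipped, collapse = ", "))
    features <- features[, !const, drop = FALSE]
  }
  is_vol <- grepl("_volume$", colnames(features))
  if (any(is_vol) && is.null(tiv)) {
    stop("tiv is required when volume features are present")
  }
  base_X <- cbind(1, as.numeric(genotype), covars$age, covars$sex,
                  covars$education)
  est <- tval <- pval <- stats::setNames(numeric(ncol(features)),
                                         colnames(features))
  if (any(!is_vol)) {
    f <- batch_lm(base_X, features[, !is_vol, drop = FALSE], coef = 2L)
    est[!is_vol] <- f$estimate; tval[!is_vol] <- f$t; pval[!is_vol] <- f$p
  }
  if (any(is_vol)) {
    f <- batch_lm(cbind(base_X, tiv), features[, is_vol, drop = FALSE],
                  coef = 2L)
    est[is_vol] <- f$estimate; tval[is_vol] <- f$t; pval[is_vol] <- f$p
  }
  out <- data.frame(feature = colnames(features), estimate = est, t = tval,
                    p = pval, p_adj = stats::p.adjust(pval, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$reject <- out$p_adj < alpha
  attr(out, "skipped") <- skipped
  out
}

interaction_design <- function(apoe, mapt, covars) {
  covars <- as.data.frame(covars)
  cells <- table(factor(apoe, levels = 0:1), factor(mapt, levels = 0:1))
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    stop("genotype cell APOE", c("-", "+")[bad[1]], "/MAPT",
         c("-", "+")[bad[2]], " has ", cells[bad[1], bad[2]],
         " participants (need >= 2)")
  }
  X <- cbind(intercept = 1, apoe = as.numeric(apoe), mapt = as.numeric(mapt),
             apoe_x_mapt = as.numeric(apoe) * as.numeric(mapt),
             age = covars$age, sex = covars$sex,
             education = covars$education)
  X
}

#' Gene-gene interaction GLM on intra-cluster distances
#'
#' Per cluster, fits `distance ~ apoe + mapt + apoe:mapt + age + sex +
#' education` by ordinary least squares (genotypes coded 0/1, product
#' interaction) and tests the interaction term two-sided. Bonferroni
#' correction is applied across clusters. Clusters whose distances have zero
#' residual variance are flagged degenerate (t reported as NA).
#'
#' @param distances participants x clusters matrix from
#'   [intra_cluster_distances()] (or any per-participant outcome matrix).
#' @param apoe,mapt binary carrier flags; every genotype cell needs >= 2
#'   participants.
#' @param covars data.frame with `age`, `sex`, `education`.
#' @param alpha significance threshold applied to Bonferroni-adjusted
#'   interaction p-values.
#' @return list with `terms` (long data.frame: cluster, term, estimate, se,
#'   t, p) and `interaction` (per-cluster data.frame: cluster, estimate, t,
#'   p, p_bonf, reject, degenerate).
#' @export
interaction_glm <- function(distances, apoe, mapt, covars, alpha = 0.05) {
  Y <- as.matrix(distances)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cluster", seq_len(ncol(Y)))
  stop_if_not_finite(Y, "distances")
  X <- interaction_design(apoe, mapt, covars)
  fit <- batch_lm(X, Y)
  terms <- data.frame(cluster = rep(colnames(Y), each = ncol(X)),
                      term = rep(colnames(X), ncol(Y)),
                      estimate = as.vector(fit$estimate),
                      se = as.vector(fit$se),
                      t = as.vector(fit$t),
                      p = as.vector(fit$p),
                      row.names = NULL, stringsAsFactors = FALSE)
  j <- which(colnames(X) == "apoe_x_mapt")
  inter <- data.frame(cluster = colnames(Y),
                      estimate = fit$estimate[j, ],
                      t = fit$t[j, ],
                      p = fit$p[j, ],
                      p_bonf = pmin(1, fit$p[j, ] * ncol(Y)),
                      degenerate = fit$degenerate,
                      row.names = NULL, stringsAsFactors = FALSE)
  inter$reject <- !is.na(inter$p_bonf) & inter$p_bonf < alpha
  list(terms = terms, interaction = inter, n = nrow(Y), df = fit$df)
}

#' Interaction GLM on a cluster's mean cortical metric
#'
#' Averages one cortical metric over the regions belonging to a cluster
#' (per participant) and feeds the mean into the same interaction GLM as
#' [interaction_glm()]. With a single-region cluster this reduces to a
#' per-region GLM.
#'
#' @param features feature matrix with canonical names.
#' @param assignment a [assign_regions()] result.
#' @param cluster cluster index.
#' @param metric one of [cortical_metrics()].
#' @param apoe,mapt,covars as in [interaction_glm()].
#' @return data.frame of term estimates/t/p for the single model, with
#'   attribute `degenerate`.
#' @export
cluster_metric_glm <- function(features, assignment, cluster, metric, apoe,
                               mapt, covars) {
  if (!metric %in% cortical_metrics()) stop("unknown metric: ", metric)
  members <- names(assignment$cluster)[assignment$cluster == cluster]
  if (!length(members)) stop("cluster ", cluster, " is empty")
  cols <- paste(members, metric, sep = "_")
  y <- rowMeans(as.matrix(features)[, cols, drop = FALSE])
  X <- interaction_design(apoe, mapt, covars)
  fit <- batch_lm(X, matrix(y, ncol = 1))
  out <- data.frame(term = colnames(X), estimate = fit$estimate[, 1],
                    se = fit$se[, 1], t = fit$t[, 1], p = fit$p[, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- fit$degenerate[1]
  out
}
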