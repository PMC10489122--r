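#' Stratified fold assignment for cross-validation
#'
#' Randomly divides participants into `k` folds so that every fold has almost
#' the same class proportion as the whole sample: per-fold sizes differ by at
#' most one, and per-fold counts of each class differ by at most one.
#'
#' @param labels binary vector (0/1).
#' @param k number of folds; every class must have at least `k` members.
#' @param seed optional integer seed; identical seeds give identical
#'   assignments.
#' @return integer vector of fold ids in `1..k`, one per participant.
#' @examples
#' f <- stratified_folds(rep(c(1, 0), c(27, 117)), k = 5, seed = 1)
#' table(f)
#' @export
stratified_folds <- function(labels, k = 5, seed = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (k < 1) stop("k must be >= 1")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k)) {
    stop("every class needs >= k members (have ",
         paste(counts, collapse = "/"), ", k = ", k, ")")
  }
  with_seed(seed, {
    fold <- integer(n)
    load <- integer(k)
    for (cls in c(1L, 0L)) {
      idx <- sample(which(labels == cls))
      nc <- length(idx)
      base <- nc %/% k
      rem <- nc %% k
      per_fold <- rep(base, k)
      if (rem > 0) {
        lightest <- order(load, sample(k))[seq_len(rem)]
        per_fold[lightest] <- per_fold[lightest] + 1L
      }
      fold[idx] <- rep.int(seq_len(k), per_fold)
      load <- load + per_fold
    }
    fold
  })
}

#' Confusion counts from pooled predictions
#'
#' @param predicted,actual binary vectors (0/1) of equal length.
#' @return named integer vector `tp` (hit), `fn` (miss), `tn` (correct
#'   rejection), `fp` (false alarm).
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  c(tp = sum(predicted == 1 & actual == 1),
    fn = sum(predicted == 0 & actual == 1),
    tn = sum(predicted == 0 & actual == 0),
    fp = sum(predicted == 1 & actual == 0))
}

#' Reconstruct the integer confusion matrix behind printed rates
#'
#' Given a sensitivity and specificity printed at fixed precision and the
#' class sizes, finds the integer counts (TP, FN, TN, FP) whose rates round
#' (half away from zero) to the printed values; errors unless the solution is
#' unique. Used to turn published classification tables into worked examples.
#'
#' @param sensitivity,specificity printed rates.
#' @param n_pos,n_neg class sizes.
#' @param digits printed precision.
#' @return named integer vector as in [confusion_counts()].
#' @examples
#' confusion_from_rates(0.52, 0.88, n_pos = 27, n_neg = 117)
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg,
                                 digits = 2) {
  tp <- which(round_half_up((0:n_pos) / n_pos, digits) == sensitivity) - 1L
  tn <- which(round_half_up((0:n_neg) / n_neg, digits) == specificity) - 1L
  if (length(tp) != 1L || length(tn) != 1L) {
    stop("printed rates do not determine a unique confusion matrix (",
         length(tp), " TP and ", length(tn), " TN candidates)")
  }
  c(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

ratio_or_zero <- function(num, den, name, flags) {
  if (den == 0) {
    flags$undefined <- c(flags$undefined, name)
    flags$value <- 0
  } else {
    flags$value <- num / den
  }
  flags
}

#' Classification performance metrics from confusion counts
#'
#' Implements accuracy = (TP+TN)/(TP+FN+TN+FP), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN) and the
#' F-score = 2 PPV sensitivity / (PPV + sensitivity), plus the area under
#' the ROC curve computed from pooled decision values (Mann-Whitney form,
#' midranks for ties). Ratios with a zero denominator are reported as 0 and
#' listed in `undefined`.
#'
#' @param counts named vector from [confusion_counts()].
#' @param decision_values optional pooled decision values for AUC.
#' @param labels binary labels matching `decision_values`.
#' @return object of class `classification_report`: list with `metrics`
#'   (named numeric), `counts`, and `undefined` (character).
#' @examples
#' compute_metrics(confusion_from_rates(0.52, 0.88, 27, 117))
#' @export
compute_metrics <- function(counts, decision_values = NULL, labels = NULL) {
  counts <- counts[c("tp", "fn", "tn", "fp")]
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  tn <- counts[["tn"]]; fp <- counts[["fp"]]
  n <- tp + fn + tn + fp
  undefined <- character()
  rat <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  accuracy <- rat(tp + tn, n, "accuracy")
  sensitivity <- rat(tp, tp + fn, "sensitivity")
  specificity <- rat(tn, tn + fp, "specificity")
  ppv <- rat(tp, tp + fp, "ppv")
  npv <- rat(tn, tn + fn, "npv")
  f_score <- rat(2 * ppv * sensitivity, ppv + sensitivity, "f_score")
  auc <- if (!is.null(decision_values)) {
    rank_auc(decision_values, labels)
  } else NA_real_
  structure(list(metrics = c(accuracy = accuracy, sensitivity = sensitivity,
                             specificity = specificity, auc = auc, ppv = ppv,
                             npv = npv, f_score = f_score),
                 counts = counts, undefined = undefined),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (TP", x$counts[["tp"]], "FN", x$counts[["fn"]],
      "TN", x$counts[["tn"]], "FP", x$counts[["fp"]], ")\n")
  print(round_half_up(x$metrics, 2))
  if (length(x$undefined)) {
    cat("undefined (0/0 reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

# Fit a linear SVM and return the hyperplane (w, b) oriented so that
# w.x + b > 0 predicts class 1.
fit_linear_svm <- function(x, y, C, engine) {
  if (engine == "dcd") {
    fit <- dcd_linear_svm(x, 2 * y - 1, C)
    list(w = fit$w, b = fit$b)
  } else {
    m <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    b <- -m$rho
    # libsvm orients decision values toward the first class label seen; flip
    # so positive decision values mean class 1
    if (m$labels[1] == which(m$levels == "0")) {
      w <- -w
      b <- -b
    }
    list(w = w, b = b)
  }
}

#' Cross-validated linear-SVM genotype classification
#'
#' Stratified k-fold cross-validation of a soft-margin linear SVM (C = 1 by
#' default). Within each fold the training split alone is screened with the
#' covariate-adjusted GLM ([select_and_normalize()]), both splits are
#' z-scored with training statistics, the SVM is fit on the training split
#' and the held-out rows are predicted. Held-out predictions are pooled over
#' folds into a single confusion matrix before any metric is computed. If a
#' fold keeps zero features it predicts the training majority class (decision
#' value 0) and is recorded in `zero_feature_folds`.
#'
#' @param features numeric matrix (participants x named features).
#' @param labels binary vector (0/1).
#' @param covars data.frame with `age`, `sex`, `education`.
#' @param k folds (default 5, must be >= 2).
#' @param C soft-margin cost.
#' @param alpha screening threshold.
#' @param seed optional seed controlling fold assignment (and the dcd
#'   engine's coordinate shuffles).
#' @param engine `"libsvm"` (via e1071, default) or `"dcd"` (built-in dual
#'   coordinate descent; much faster in permutation loops, same model up to
#'   intercept regularization).
#' @param folds optional precomputed fold assignment.
#' @return object of class `cv_result`: list with `report`
#'   (a [compute_metrics()] report with pooled AUC), `predicted`,
#'   `decision_values`, `folds`, `weights` (fold-averaged hyperplane
#'   coefficients over the full feature space, zeros for unselected
#'   features), `fold_weights`, `selections` (per-fold selection reports)
#'   and `zero_feature_folds`.
#' @examples
#' coh <- generate_cohort(c(30, 6, 17, 8), seed = 1)
#' X <- generate_features(coh, effect_config(seed = 2))
#' res <- cv_classify(X, coh$apoe_pos, coh[c("age", "sex", "education")],
#'                    seed = 3)
#' res$report
#' @export
cv_classify <- function(features, labels, covars, k = 5, C = 1,
                        alpha = 0.05, seed = NULL,
                        engine = c("libsvm", "dcd"), folds = NULL) {
  engine <- match.arg(engine)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  covars <- cbind(age = covars[["age"]], sex = covars[["sex"]],
                  education = covars[["education"]])
  n <- nrow(features)
  if (k < 2) stop("cross-validation needs k >= 2")
  with_seed(seed, {
    if (is.null(folds)) folds <- stratified_folds(labels, k)
    predicted <- integer(n)
    decision <- numeric(n)
    p <- ncol(features)
    fold_weights <- matrix(0, k, p, dimnames = list(NULL, colnames(features)))
    fold_b <- numeric(k)
    selections <- vector("list", k)
    zero_feature_folds <- integer(0)
    for (f in seq_len(k)) {
      tr <- folds != f
      te <- !tr
      sel <- select_and_normalize(features[tr, , drop = FALSE], labels[tr],
                                  covars[tr, , drop = FALSE],
                                  apply_to = features[te, , drop = FALSE],
                                  alpha = alpha)
      selections[[f]] <- sel$selection
      if (ncol(sel$train) == 0L) {
        maj <- as.integer(mean(labels[tr]) >= 0.5)
        predicted[te] <- maj
        decision[te] <- 0
        zero_feature_folds <- c(zero_feature_folds, f)
        next
      }
      fit <- fit_linear_svm(sel$train, labels[tr], C, engine)
      dv <- drop(sel$apply_to %*% fit$w) + fit$b
      predicted[te] <- as.integer(dv > 0)
      decision[te] <- dv
      fold_weights[f, colnames(sel$train)] <- fit$w
      fold_b[f] <- fit$b
    }
    counts <- confusion_counts(predicted, labels)
    report <- compute_metrics(counts, decision, labels)
    structure(list(report = report, predicted = predicted,
                   decision_values = decision, folds = folds,
                   weights = colMeans(fold_weights),
                   fold_weights = fold_weights, fold_b = fold_b,
                   selections = selections,
                   zero_feature_folds = zero_feature_folds,
                   engine = engine),
              class = "cv_result")
  })
}

#' Permutation significance of classification metrics
#'
#' Re-runs the full cross-validated pipeline (screening included) `n_perm`
#' times with labels permuted across participants without replacement, and
#' compares each observed metric with its null distribution. The default
#' `tie_rule = "strict"` follows the printed definition, p = proportion of
#' permutations with a value strictly higher than the observed one (this can
#' yield p = 0 and is anti-conservative under ties); `"plus_one"` applies the
#' standard correction p = (#\{null >= observed\} + 1) / (n_perm + 1), which
#' is a valid p-value.
#'
#' @inheritParams cv_classify
#' @param n_perm number of permutations (>= 1).
#' @param tie_rule `"strict"` or `"plus_one"` (see Details).
#' @return list with `observed` (the unpermuted `cv_result`), `p` (named
#'   per-metric p-values), `null` (n_perm x metric matrix) and `tie_rule`.
#' @export
permutation_test <- function(features, labels, covars, k = 5, C = 1,
                             alpha = 0.05, n_perm = 1000, seed = NULL,
                             engine = c("libsvm", "dcd"),
                             tie_rule = c("strict", "plus_one")) {
  engine <- match.arg(engine)
  tie_rule <- match.arg(tie_rule)
  if (n_perm < 1) stop("n_perm must be >= 1")
  with_seed(seed, {
    observed <- cv_classify(features, labels, covars, k = k, C = C,
                            alpha = alpha, engine = engine)
    obs <- observed$report$metrics
    null_mat <- matrix(NA_real_, n_perm, length(obs),
                       dimnames = list(NULL, names(obs)))
    for (b in seq_len(n_perm)) {
      yp <- sample(labels)
      r <- cv_classify(features, yp, covars, k = k, C = C, alpha = alpha,
                       engine = engine)
      null_mat[b, ] <- r$report$metrics
    }
    p <- if (tie_rule == "strict") {
      colMeans(sweep(null_mat, 2, obs, `>`))
    } else {
      (colSums(sweep(null_mat, 2, obs, `>=`)) + 1) / (n_perm + 1)
    }
    list(observed = observed, p = p, null = null_mat, tie_rule = tie_rule)
  })
}

#' Summarize SVM hyperplane weights into region and metric maps
#'
#' Region importance is the sum over a region's metrics of the absolute
#' hyperplane coefficients; per-metric aggregates are the sums of the
#' positive and of the negative coefficients across regions, kept separate.
#' A matrix of per-fold weight vectors is averaged first (features never
#' selected contribute 0).
#'
#' @param weights named numeric vector of hyperplane coefficients on the
#'   canonical feature naming, or a folds x features matrix thereof.
#' @return object of class `weight_map`: list with `feature`
#'   (feature/weight/hemi/region/metric), `region_importance` (region,
#'   importance; sorted decreasing) and `metric_sums` (metric, positive_sum,
#'   negative_sum).
#' @examples
#' w <- c(left_precuneus_thickness = -0.4, right_insula_curvature = 0.2)
#' summarize_weights(w)$region_importance
#' @export
summarize_weights <- function(weights) {
  if (is.matrix(weights)) weights <- colMeans(weights)
  if (is.null(names(weights))) stop("weights must be named")
  info <- parse_feature_name(names(weights))
  info$weight <- as.numeric(weights)
  region_importance <- stats::aggregate(abs(weight) ~ region, data = info,
                                        FUN = sum)
  names(region_importance) <- c("region", "importance")
  region_importance <-
    region_importance[order(-region_importance$importance), ]
  rownames(region_importance) <- NULL
  pos <- stats::aggregate(pmax(weight, 0) ~ metric, data = info, FUN = sum)
  neg <- stats::aggregate(pmin(weight, 0) ~ metric, data = info, FUN = sum)
  metric_sums <- data.frame(metric = pos$metric,
                            positive_sum = pos[[2]],
                            negative_sum = neg[[2]][match(pos$metric,
                                                          neg$metric)],
                            stringsAsFactors = FALSE)
  structure(list(feature = info[c("feature", "weight", "hemi", "region",
                                  "metric")],
                 region_importance = region_importance,
                 metric_sums = metric_sums),
            class = "weight_map")
}
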