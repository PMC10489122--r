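test_that("stratified folds balance sizes and class counts", {
  y <- rep(c(1, 0), c(27, 117))
  f <- stratified_folds(y, k = 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  sizes <- table(f)
  expect_true(all(sizes %in% 28:29))
  pos <- table(f[y == 1])
  expect_true(all(pos %in% 5:6))
  expect_identical(stratified_folds(y, k = 5, seed = 1), f)
  expect_false(identical(stratified_folds(y, k = 5, seed = 2), f))
  expect_true(all(stratified_folds(y, k = 1, seed = 3) == 1))
  expect_error(stratified_folds(rep(c(1, 0), c(3, 50)), k = 5), ">= k")
})

test_that("fold balance holds across random class mixes", {
  set.seed(4)
  for (i in 1:20) {
    n1 <- sample(6:60, 1); n0 <- sample(6:200, 1)
    y <- sample(rep(c(1, 0), c(n1, n0)))
    k <- sample(2:5, 1)
    f <- stratified_folds(y, k = k)
    expect_lte(diff(range(table(factor(f, levels = 1:k)))), 1)
    expect_lte(diff(range(table(factor(f[y == 1], levels = 1:k)))), 1)
    expect_lte(diff(range(table(factor(f[y == 0], levels = 1:k)))), 1)
  }
})

test_that("metrics match a direct counting oracle on random predictions", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    actual <- rbinom(n, 1, runif(1, 0.1, 0.9))
    predicted <- rbinom(n, 1, runif(1, 0.1, 0.9))
    rep_ <- compute_metrics(confusion_counts(predicted, actual))
    oracle <- metric_oracle(predicted, actual)
    expect_equal(rep_$metrics[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("degenerate counts report zeros with flags and F keeps its identity", {
  r <- compute_metrics(c(tp = 0, fn = 0, tn = 8, fp = 0))
  expect_equal(unname(r$metrics["sensitivity"]), 0)
  expect_equal(unname(r$metrics["specificity"]), 1)
  expect_true(all(c("sensitivity", "ppv", "f_score") %in% r$undefined))
  # PPV = sensitivity = 0.5 gives F = 0.5 (harmonic-mean identity)
  r2 <- compute_metrics(c(tp = 1, fn = 1, tn = 5, fp = 1))
  expect_equal(unname(r2$metrics["f_score"]), 0.5)
  set.seed(6)
  for (i in 1:20) {
    counts <- c(tp = rpois(1, 20), fn = rpois(1, 20), tn = rpois(1, 40),
                fp = rpois(1, 10))
    m <- compute_metrics(counts)$metrics
    expect_equal(unname(m["accuracy"]),
                 (counts[["tp"]] + counts[["tn"]]) / sum(counts),
                 tolerance = 1e-12)
    if (m["ppv"] + m["sensitivity"] > 0) {
      expect_equal(unname(m["f_score"]),
                   unname(2 * m["ppv"] * m["sensitivity"] /
                            (m["ppv"] + m["sensitivity"])),
                   tolerance = 1e-12)
    }
  }
})

test_that("pooled AUC equals pROC on random decision values", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(morphrisk:::rank_auc(s, y),
                 as.numeric(pROC::auc(y, s, quiet = TRUE,
                                      direction = "<")),
                 tolerance = 1e-10)
  }
})

test_that("cross-validation separates a strongly planted effect", {
  coh <- generate_cohort(c(40, 0, 0, 40), seed = 8)
  cfg <- effect_config(main_effect_apoe = c(0, -2, 2, 2, 0),
                       main_effect_mapt = rep(0, 5),
                       interaction_effect = rep(0, 5), seed = 9)
  X <- generate_features(coh, cfg)
  for (engine in c("libsvm", "dcd")) {
    res <- cv_classify(X, coh$apoe_pos, default_covars(coh), seed = 10,
                       engine = engine)
    expect_gte(res$report$metrics[["accuracy"]], 0.95)
  }
  a <- cv_classify(X, coh$apoe_pos, default_covars(coh), seed = 10)
  b <- cv_classify(X, coh$apoe_pos, default_covars(coh), seed = 10,
                   engine = "dcd")
  expect_gte(mean(a$predicted == b$predicted), 0.95)
  # pooled predictions cover every participant exactly once
  expect_equal(length(a$predicted), nrow(X))
  expect_setequal(unique(a$folds), 1:5)
})

test_that("with no signal the pooled AUC stays near one half", {
  aucs <- vapply(1:20, function(s) {
    coh <- generate_cohort(c(36, 36, 36, 36), seed = 700 + s)
    X <- generate_features(coh, null_config(800 + s))
    cv_classify(X, coh$apoe_pos, default_covars(coh), seed = 900 + s,
                engine = "dcd")$report$metrics[["auc"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("folds keeping zero features fall back to the majority class", {
  coh <- generate_cohort(c(20, 10, 10, 10), seed = 11)
  X <- generate_features(coh, null_config(12))
  res <- cv_classify(X, coh$apoe_pos, default_covars(coh), seed = 13,
                     alpha = 1e-12)
  expect_equal(res$zero_feature_folds, 1:5)
  expect_true(all(res$predicted == 0))  # negatives are the majority
  expect_equal(unname(res$report$metrics["accuracy"]), mean(coh$apoe_pos == 0))
})

test_that("permutation p-values honour the strict and plus-one tie rules", {
  # strong signal: observed above every null draw -> strict p = 0
  coh <- generate_cohort(c(15, 0, 0, 15), seed = 14)
  cfg <- effect_config(main_effect_apoe = c(0, -3, 3, 3, 0),
                       main_effect_mapt = rep(0, 5),
                       interaction_effect = rep(0, 5), seed = 15)
  X <- generate_features(coh, cfg)
  pt1 <- permutation_test(X, coh$apoe_pos, default_covars(coh), n_perm = 19,
                          seed = 16, engine = "dcd")
  expect_equal(unname(pt1$p["accuracy"]), 0)
  pt2 <- permutation_test(X, coh$apoe_pos, default_covars(coh), n_perm = 19,
                          seed = 16, engine = "dcd", tie_rule = "plus_one")
  expect_equal(unname(pt2$p["accuracy"]), 1 / 20)

  # all-tied metric: strict rule gives p = 0, plus-one gives p = 1
  coh2 <- generate_cohort(c(20, 10, 10, 10), seed = 17)
  X2 <- generate_features(coh2, null_config(18))
  pts <- permutation_test(X2, coh2$apoe_pos, default_covars(coh2),
                          n_perm = 9, seed = 19, alpha = 1e-12,
                          engine = "dcd")
  expect_equal(unname(pts$p["accuracy"]), 0)
  ptp <- permutation_test(X2, coh2$apoe_pos, default_covars(coh2),
                          n_perm = 9, seed = 19, alpha = 1e-12,
                          engine = "dcd", tie_rule = "plus_one")
  expect_equal(unname(ptp$p["accuracy"]), 1)
})

test_that("weight summaries aggregate regions and metrics as specified", {
  w <- c(left_precuneus_thickness = -0.4)
  wm <- summarize_weights(w)
  expect_equal(wm$region_importance$importance, 0.4)
  expect_equal(wm$region_importance$region, "left_precuneus")
  ms <- wm$metric_sums
  expect_equal(ms$negative_sum[ms$metric == "thickness"], -0.4)
  expect_equal(ms$positive_sum[ms$metric == "thickness"], 0)

  w2 <- c(left_insula_area = 0.3, left_insula_thickness = -0.2,
          right_insula_curvature = 0.1, left_precuneus_folding_index = -0.35,
          right_hippocampus_volume = 0.05)
  wm2 <- summarize_weights(w2)
  imp <- setNames(wm2$region_importance$importance,
                  wm2$region_importance$region)
  expect_equal(unname(imp["left_insula"]), 0.5)
  expect_equal(unname(imp["left_precuneus"]), 0.35)
  expect_equal(wm2$region_importance$region[1], "left_insula")
  ms2 <- wm2$metric_sums
  expect_equal(ms2$positive_sum[ms2$metric == "area"], 0.3)
  expect_equal(ms2$negative_sum[ms2$metric == "folding_index"], -0.35)
  expect_error(summarize_weights(c(left_nowhere_thickness = 1)),
               "unknown region")

  # fold matrix averaging: unselected features contribute zero
  W <- rbind(c(left_insula_area = 0.4), c(left_insula_area = 0))
  expect_equal(summarize_weights(W)$feature$weight, 0.2)

  expect_true(all(summarize_weights(w2)$region_importance$importance >= 0))
  expect_true(all(ms2$positive_sum >= 0) && all(ms2$negative_sum <= 0))
})

test_that("with no class structure region rankings are unstable across seeds", {
  coh <- generate_cohort(c(36, 36, 36, 36), seed = 20)
  X <- generate_features(coh, null_config(21))
  ranks <- sapply(1:4, function(s) {
    set.seed(50 + s)
    y <- sample(coh$apoe_pos)
    res <- cv_classify(X, y, default_covars(coh), seed = 60 + s,
                       engine = "dcd")
    wm <- summarize_weights(res$weights)
    imp <- setNames(wm$region_importance$importance,
                    wm$region_importance$region)
    rank(imp[cortical_regions()])
  })
  cors <- cor(ranks, method = "spearman")
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.5)
})
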