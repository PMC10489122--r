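test_that("multiple-testing corrections match brute-force definitions", {
  set.seed(20)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    expect_equal(p.adjust(p, "bonferroni"), bonferroni_oracle(p),
                 tolerance = 1e-12)
  }
  coh <- generate_cohort(c(10, 6, 6, 6), seed = 21)
  X <- generate_features(coh, effect_config(seed = 22))[, 1:20]
  scan <- univariate_scan(X, coh$apoe_pos, default_covars(coh),
                          tiv = coh$tiv)
  expect_equal(scan$p_adj, bh_oracle(scan$p), tolerance = 1e-12)
  # m = 1: adjusted p equals raw p
  scan1 <- univariate_scan(X[, 1, drop = FALSE], coh$apoe_pos,
                           default_covars(coh))
  expect_equal(scan1$p_adj, scan1$p)
})

test_that("interaction GLM terms match a normal-equations oracle", {
  coh <- generate_cohort(c(10, 6, 6, 6), seed = 23)
  set.seed(24)
  D <- matrix(rnorm(28 * 3), 28, 3,
              dimnames = list(NULL, paste0("cluster", 1:3)))
  res <- interaction_glm(D, coh$apoe_pos, coh$mapt_pos, default_covars(coh))
  X <- cbind(1, coh$apoe_pos, coh$mapt_pos, coh$apoe_pos * coh$mapt_pos,
             coh$age, coh$sex, coh$education)
  for (k in 1:3) {
    oracle <- ols_oracle(X, D[, k])
    got <- res$terms[res$terms$cluster == paste0("cluster", k), ]
    expect_equal(got$estimate, unname(oracle$beta), tolerance = 1e-8)
    expect_equal(got$t, unname(oracle$t), tolerance = 1e-8)
    expect_equal(got$p, unname(oracle$p), tolerance = 1e-8)
  }
  expect_equal(res$interaction$p_bonf, bonferroni_oracle(res$interaction$p),
               tolerance = 1e-12)
  # degenerate outcome: constant distances -> flagged, t is NA
  D2 <- D; D2[, 2] <- 1.7
  res2 <- interaction_glm(D2, coh$apoe_pos, coh$mapt_pos,
                          default_covars(coh))
  expect_true(res2$interaction$degenerate[2])
  expect_true(is.na(res2$interaction$t[2]))
})

test_that("an empty genotype cell is rejected by name", {
  coh <- generate_cohort(c(20, 10, 10, 0), seed = 25)
  D <- matrix(rnorm(40), 40, 1)
  expect_error(interaction_glm(D, coh$apoe_pos, coh$mapt_pos,
                               default_covars(coh)),
               "APOE\\+/MAPT\\+")
})

test_that("a global-null univariate scan rarely rejects after FDR", {
  zero_runs <- vapply(1:10, function(s) {
    coh <- generate_cohort(seed = 1100 + s)
    X <- generate_features(coh, null_config(1200 + s))
    scan <- univariate_scan(X, coh$apoe_pos, default_covars(coh),
                            tiv = coh$tiv)
    sum(scan$reject) == 0
  }, logical(1))
  expect_gte(mean(zero_runs), 0.9)
})

test_that("a single massive planted effect survives FDR and is the right feature", {
  coh <- generate_cohort(seed = 26)
  X <- generate_features(coh, null_config(27))
  j <- "right_fusiform_curvature"
  X[, j] <- X[, j] + coh$apoe_pos * 5 * sd(X[, j])
  scan <- univariate_scan(X, coh$apoe_pos, default_covars(coh), tiv = coh$tiv)
  expect_true(scan$reject[scan$feature == j])
  expect_lte(sum(scan$reject), 3)
})

test_that("volume features require and use the TIV covariate", {
  coh <- generate_cohort(c(10, 6, 6, 6), seed = 28)
  X <- generate_features(coh, effect_config(seed = 29))
  vol <- X[, grep("_volume$", colnames(X)), drop = FALSE]
  expect_error(univariate_scan(vol, coh$apoe_pos, default_covars(coh)),
               "tiv")
  scan <- univariate_scan(vol[, 1, drop = FALSE], coh$apoe_pos,
                          default_covars(coh), tiv = coh$tiv)
  Xd <- cbind(1, coh$apoe_pos, coh$age, coh$sex, coh$education, coh$tiv)
  expect_equal(scan$p, ols_oracle(Xd, vol[, 1])$p[2], tolerance = 1e-8)
})

test_that("the interaction term is calibrated under the null", {
  set.seed(30)
  coh <- generate_cohort(seed = 31)
  X <- cbind(1, coh$apoe_pos, coh$mapt_pos, coh$apoe_pos * coh$mapt_pos,
             coh$age, coh$sex, coh$education)
  p <- vapply(1:500, function(i) {
    D <- matrix(rnorm(144), 144, 1)
    interaction_glm(D, coh$apoe_pos, coh$mapt_pos,
                    default_covars(coh))$interaction$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("a planted double-carrier distance shift is detected in the right cluster", {
  set.seed(32)
  coh <- generate_cohort(seed = 33)
  hits <- 0; sign_ok <- 0; n_sim <- 120
  for (i in seq_len(n_sim)) {
    D <- matrix(rnorm(144 * 4), 144, 4,
                dimnames = list(NULL, paste0("cluster", 1:4)))
    D[, 1] <- D[, 1] + coh$apoe_pos * coh$mapt_pos  # +1 residual sd
    res <- interaction_glm(D, coh$apoe_pos, coh$mapt_pos,
                           default_covars(coh))
    if (res$interaction$reject[1]) {
      hits <- hits + 1
      sign_ok <- sign_ok + (res$interaction$estimate[1] > 0)
    }
  }
  expect_gt(hits / n_sim, 0.2)       # clearly above the 1.25% Bonferroni level
  expect_equal(sign_ok, hits)        # recovered sign always matches the plant
})

test_that("cluster metric GLM reduces to a per-region GLM for singletons", {
  coh <- generate_cohort(c(10, 6, 6, 6), seed = 34)
  X <- generate_features(coh, effect_config(seed = 35))
  assignment <- structure(list(cluster = c(left_insula = 1L,
                                           right_insula = 2L),
                               centroids = matrix(0, 2, 4),
                               sizes = c(1L, 1L)),
                          class = "cluster_assignment")
  got <- cluster_metric_glm(X, assignment, 1, "thickness", coh$apoe_pos,
                            coh$mapt_pos, default_covars(coh))
  Xd <- cbind(1, coh$apoe_pos, coh$mapt_pos, coh$apoe_pos * coh$mapt_pos,
              coh$age, coh$sex, coh$education)
  oracle <- ols_oracle(Xd, X[, "left_insula_thickness"])
  expect_equal(got$t, unname(oracle$t), tolerance = 1e-8)
  expect_error(cluster_metric_glm(X, assignment, 3, "thickness",
                                  coh$apoe_pos, coh$mapt_pos,
                                  default_covars(coh)), "empty")
  expect_error(cluster_metric_glm(X, assignment, 1, "density",
                                  coh$apoe_pos, coh$mapt_pos,
                                  default_covars(coh)), "unknown metric")
})

test_that("a curvature-and-folding interaction shows up in those metrics only", {
  coh <- generate_cohort(seed = 36)
  cfg <- effect_config(main_effect_apoe = rep(0, 5),
                       main_effect_mapt = rep(0, 5),
                       interaction_effect = c(area = 0, thickness = 0,
                                              curvature = 1.2,
                                              folding_index = 1.2,
                                              volume = 0),
                       seed = 37)
  X <- generate_features(coh, cfg)
  zp <- zscore_profiles(X)
  g <- train_ghsom(zp$profiles, seed = 38)
  a <- assign_regions(g, zp$profiles)
  # the cluster holding the designated interaction regions
  k <- as.integer(names(which.max(table(
    a$cluster[cfg$interaction_regions]))))
  pvals <- vapply(cortical_metrics(), function(m) {
    res <- cluster_metric_glm(X, a, k, m, coh$apoe_pos, coh$mapt_pos,
                              default_covars(coh))
    res$p[res$term == "apoe_x_mapt"]
  }, numeric(1))
  expect_lt(pvals[["curvature"]], 0.05)
  expect_lt(pvals[["folding_index"]], 0.05)
  expect_gt(pvals[["area"]], 0.05)
  expect_gt(pvals[["thickness"]], 0.05)
})
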