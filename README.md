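# morphrisk

Detecting effects of Alzheimer's-disease risk genotypes — *APOE* ε4 and
*MAPT* rs242557 A — on regional cortical morphology in young healthy adults,
where the effects are too subtle for mass-univariate tests to survive
multiple-comparison correction.

The package is aimed at imaging-genetics analysts working with regional
morphometry tables (e.g. FreeSurfer Desikan–Killiany parcellations: 68
cortical regions × {area, thickness, mean curvature, folding index} plus 14
subcortical volumes, 286 features per participant). It implements the full
computational chain:

1. **Synthetic cohorts** (`generate_cohort()`, `generate_features()`) — a
   generator with the four-genotype-group structure (default 83/11/34/16
   participants, ages 18–24), configurable planted main effects and an
   *APOE*×*MAPT* interaction restricted to one morphological cluster, so the
   whole pipeline is testable without any data download.
2. **Curvature metrics and I/O** (`mean_curvature()`, `folding_index()`,
   `read_freesurfer_stats()`, `read_feature_table()`) — H = (κ₁+κ₂)/2,
   FI = |κ₁|(|κ₁|−|κ₂|) with magnitude ordering so FI ≥ 0, plus readers for
   FreeSurfer-dialect `aparc`/`aseg` stats files and a validated TSV feature
   table.
3. **Leakage-guarded screening** (`select_and_normalize()`) — per-fold
   covariate-adjusted GLM screen (`feature ~ genotype + age + sex +
   education`, keep p < 0.05 on the training split only) and z-scoring with
   training statistics.
4. **Classification** (`cv_classify()`, `permutation_test()`,
   `summarize_weights()`) — stratified 5-fold linear SVM (C = 1), held-out
   predictions pooled into one confusion matrix, seven metrics
   (accuracy, sensitivity, specificity, AUC, PPV, NPV, F-score), label
   permutation with the full pipeline re-run per permutation, and hyperplane
   weight maps summarized per region (Σ|w|) and per metric (positive and
   negative sums kept separate).
5. **Morphological clustering** (`zscore_profiles()`, `train_ghsom()`,
   `assign_regions()`, `intra_cluster_distances()`) — a growing hierarchical
   self-organizing map clusters the 68 regions into morphological profiles;
   each participant then gets an intra-cluster distance: the mean Euclidean
   distance of their z-scored region vectors from each cluster centroid.
6. **Interaction statistics** (`interaction_glm()`, `cluster_metric_glm()`,
   `univariate_scan()`) — `distance ~ apoe + mapt + apoe:mapt + age + sex +
   education` per cluster with Bonferroni correction, follow-up cluster-mean
   metric models, and a stand-alone BH-FDR univariate scan (volumes adjusted
   for total intracranial volume).

## A worked example

```r
library(morphrisk)

coh <- generate_cohort(seed = 1)     # 144 participants: 27 APOE+, 50 MAPT+
X   <- generate_features(coh, effect_config(seed = 2))

cv  <- cv_classify(X, coh$apoe_pos, coh[c("age", "sex", "education")], seed = 3)
cv$report
#> Classification report (TP 15 FN 12 TN 110 FP 7 )
#>    accuracy sensitivity specificity         auc         ppv         npv
#>        0.87        0.56        0.94        0.86        0.68        0.90
#>     f_score
#>        0.61
```

The pooled confusion matrix says 15 of 27 carriers and 110 of 117
non-carriers were recovered from morphology alone. The weight maps show the
direction of the signal — thickness coefficients are overwhelmingly negative
(carriers have thinner cortex) while curvature and folding-index coefficients
are positive (more convoluted cortex):

```r
summarize_weights(cv$weights)$metric_sums
#>          metric positive_sum negative_sum
#> 1          area   0.11588950  -0.03657671
#> 2     curvature   1.31375215  -0.12831266
#> 3 folding_index   1.85981382  -0.03429630
#> 4     thickness   0.03197683  -1.41113129
#> 5        volume   0.00000000   0.00000000
```

Clustering the regions and testing the per-participant deviations finds the
gene–gene interaction exactly where the generator planted it (the 34-region
temporal/insular/cingulate archetype, here cluster 3):

```r
zp <- zscore_profiles(X)
a  <- assign_regions(train_ghsom(zp$profiles, seed = 4), zp$profiles)
D  <- intra_cluster_distances(a, zp$tensor)
interaction_glm(D, coh$apoe_pos, coh$mapt_pos,
                coh[c("age", "sex", "education")])$interaction
#>    cluster estimate     t        p   p_bonf degenerate reject
#> 1 cluster1   0.0083 0.257 7.98e-01 1.00e+00      FALSE  FALSE
#> 2 cluster2   0.0395 0.815 4.16e-01 1.00e+00      FALSE  FALSE
#> 3 cluster3   0.0955 4.671 7.08e-06 2.83e-05      FALSE   TRUE
#> 4 cluster4   0.0277 0.791 4.30e-01 1.00e+00      FALSE  FALSE
```

A positive interaction estimate means carriers of *both* risk alleles deviate
most from that cluster's typical morphology. For permutation significance of
the classifier, run `permutation_test()` (1000 permutations by default; use
`engine = "dcd"` for speed).

A command-line front end over the same functions lives in
`inst/scripts/morphrisk.R` (`simulate`, `classify`, `cluster`, `interact`,
`scan` subcommands). The methods vignette
(`vignettes/morphrisk-methods.Rmd`) documents the model choices, defaults
and limitations.

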