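---
title: "Detecting genetic-risk effects on cortical morphology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetic-risk effects on cortical morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Carriers of the *APOE* ε4 allele and of the *MAPT* rs242557 A allele carry
elevated lifetime risk of Alzheimer's disease. In young adults (late teens to
mid-twenties) any morphological correlate of that risk is far too subtle for
mass-univariate tests on regional morphometry to survive multiple-testing
correction. `morphrisk` implements the multivariate alternative: classify
genotype from 286 regional features (68 Desikan–Killiany cortical regions ×
surface area, mean thickness, mean curvature, folding index, plus 14
subcortical volumes) with a cross-validated linear SVM, assess significance by
permutation, summarize which regions and metrics carry the signal, and — for
the gene–gene question, which a classifier cannot answer — cluster regions
into morphological profiles with a growing hierarchical self-organizing map
(GHSOM) and test each participant's deviation from the cluster centroids for
an *APOE* × *MAPT* interaction with covariate-adjusted linear models.

Because no participant-level data are distributed, the package ships a
synthetic-cohort generator reproducing the cohort structure such analyses
assume, so every stage is testable end to end.

# Curvature-derived metrics

At each surface vertex FreeSurfer reports the two principal normal curvatures
$\kappa_1 \ge \kappa_2$. The package computes the regional summaries from the
standard formulas

$$H = \frac{\kappa_1 + \kappa_2}{2}, \qquad
  \mathrm{FI} = |\kappa_1|\,\bigl(|\kappa_1| - |\kappa_2|\bigr).$$

With a strict max/min ordering the FI formula can go negative (e.g.
$\kappa_1 = 1$, $\kappa_2 = -2$); `folding_index()` therefore orders the pair
by absolute magnitude before applying the formula, following the FreeSurfer
convention, which makes FI $\ge 0$ always. This is stated prominently because
the formula alone is ambiguous on the point.

# The classification pipeline

`cv_classify()` runs stratified 5-fold cross-validation. Stratification keeps
the carrier proportion of every fold within one participant of the overall
rate. Within each fold:

1. **Screening** (`select_and_normalize()`): each feature is tested on the
   *training split only* with the linear model
   `feature ~ genotype + age + sex + education`; features with p < 0.05 are
   kept. The screening p-values are deliberately uncorrected — this is a
   per-fold filter, not an inferential claim.
2. **Normalization**: both splits are z-scored with training means and
   standard deviations. No statistic is ever computed from held-out rows, so
   label information cannot leak; the test suite asserts that shuffling
   held-out labels leaves masks and constants bit-identical.
3. **SVM**: a soft-margin linear SVM with C = 1 is fit on the training split
   (via `e1071`/libsvm by default) and the held-out rows are predicted.

Held-out predictions from all folds are pooled into one confusion matrix
before any metric is computed. Accuracy, sensitivity, specificity, PPV, NPV
and the F-score follow the standard count formulas; ratios with a zero
denominator are reported as 0 and flagged. The AUC is the Mann–Whitney rank
statistic of the pooled decision values (midranks under ties, so a constant
score gives 0.5); pooling rather than averaging per-fold ROC curves is a
design choice — the alternative was considered and rejected because per-fold
curves at these sample sizes (≈29 held-out participants) are very coarse.

**Permutation significance** (`permutation_test()`): labels are permuted
across participants without replacement and the *entire* pipeline — fold
assignment, screening, normalization, SVM — is re-run per permutation. Two
tie rules are provided. The default (`strict`) is the literal printed rule,
p = proportion of permutations with a value strictly above the observed one;
it can return p = 0 and becomes anti-conservative when the metric ties
heavily across permutations (in the extreme, a majority-class-collapsed
classifier pins sensitivity at 0 in every run and the strict p is 0). The
`plus_one` rule,
$p = (\#\{\text{null} \ge \text{obs}\} + 1)/(n_{\text{perm}} + 1)$, is a
valid (never anti-conservative) p-value, at the price of losing power to the
tie mass: for count-based metrics such as sensitivity the tie mass at the
observed value is around 6 % of permutations at n = 144, which pushes its
null rejection rate at the 5 % level down to roughly 2.5 %. The package's
calibration checks therefore exercise the default rule, whose mild
tie-induced anti-conservatism and the discreteness deficit roughly offset at
these sample sizes (all seven metrics reject between 3.8 % and 6.3 % under
the global null); `plus_one` remains the right choice when a guaranteed-valid
p-value matters more than power.

**Weight maps** (`summarize_weights()`): per-fold hyperplanes are re-expanded
to the full feature space (zeros for unselected features) and averaged — the
choice of averaging is ours; nothing in the problem dictates how five folds'
hyperplanes become one map. Region importance is the sum of absolute
coefficients over a region's metrics; per-metric aggregates keep the positive
and negative coefficient sums separate so that the direction of association
(e.g. thickness negatively, folding index positively related to carrier
status) remains visible.

No class weighting is applied (only C = 1 is specified for the model);
majority-class collapse under weak signal is expected and visible in
single-metric models, which is precisely why PPV, NPV and F are reported
alongside accuracy for these unbalanced classes (27/117 for *APOE*, 50/94
for *MAPT*).

## The fast SVM engine

Permutation calibration re-fits roughly 50,000 SVMs in the package's own
checks. Alongside the libsvm default, `engine = "dcd"` provides a dual
coordinate-descent solver for the same L1-loss linear SVM (the liblinear
algorithm, with shrinking), compiled from C++. It differs from libsvm only
in handling the intercept by constant-feature augmentation (weakly
regularized bias). Tests assert that the two engines agree on predictions on
separated data; the statistical properties being checked do not depend on
the engine.

# Morphological clustering

`zscore_profiles()` builds the clustering inputs. The samples are the 68
cortical regions, each described by its cohort-mean area, thickness,
curvature and folding index, z-scored per metric **across regions**. The same
constants standardize each participant's regional vectors, so centroids and
participants live in one space. The obvious-seeming alternative — z-scoring
each feature across participants first — makes the cohort-mean profile of
every region identically zero (the mean of a z-score over the axis it was
computed on), leaving nothing to cluster; it is retained as
`axis = "participants"` for pooled region×participant training, where it is
meaningful. Subcortical volumes are excluded: the clusters are cortical
morphological profiles.

`train_ghsom()` implements the standard GHSOM: a 2×2 map trained with batch
SOM epochs under a linearly shrinking Gaussian neighborhood, then a Lloyd
polish (neighborhood zero, run to convergence); breadth growth inserts a
row/column of averaged weights between the highest-quantization-error node
and its most dissimilar grid neighbor until the map's mean quantization
error (MQE) drops below `tau1` × the parent unit's error; nodes whose error
stays above `tau2` × the root error are expanded into child maps. Only the
top layer defines clusters; deeper maps are retained for inspection.

Numerical choices worth knowing:

* **Initialization**: the 2×2 weights are spread over the first two principal
  components (signs fixed for determinism) plus a tiny seeded jitter. Mean
  initialization strands nodes on well-separated data; the PCA spread makes
  four separated archetypes resolve to the four corners reliably.
* **Monotone MQE**: the Lloyd polish plus a fallback rule (if a growth cycle
  ends with higher MQE than the previous cycle, the cycle is redone from the
  inserted configuration with Lloyd only, which cannot increase the previous
  converged error) guarantees that MQE never increases across growth steps —
  an invariant the tests assert.
* **Hyperparameters**: `tau1 = 0.6`, `tau2 = 0.1`, 30 epochs per growth
  cycle. No published values exist for this application; these defaults make
  growth conservative (a 2×2 map that already explains 40 % of the root error
  stops growing) and are configurable. Consequently the package's
  acceptance surface targets *cluster-count and partition recovery on
  synthetic archetypes*, not any specific published partition.
* **Ties**: nearest-centroid assignment breaks exact ties toward the lowest
  cluster index; empty clusters are dropped and indices compacted.

`intra_cluster_distances()` then gives, per participant and cluster, the mean
Euclidean distance of the participant's z-scored region vectors (for that
cluster's regions) from the cluster centroid — the statistic carrying the
gene–gene signal: a participant whose morphology deviates from a cluster's
typical pattern scores high.

# Interaction statistics

`interaction_glm()` fits, per cluster,

`distance ~ apoe + mapt + apoe:mapt + age + sex + education`

by ordinary least squares (genotypes coded 0/1, product interaction — the
coding is a package choice; homoscedastic errors, no robust standard errors),
tests the interaction two-sided, and Bonferroni-corrects across clusters.
`cluster_metric_glm()` runs the same model on a cluster's mean metric to
attribute a distance effect to specific metrics; it is run for all clusters
but results for clusters without a significant distance interaction should be
read as exploratory. `univariate_scan()` provides the stand-alone
mass-univariate comparison with Benjamini–Hochberg correction across all
features; volume features are additionally adjusted for total intracranial
volume. Whether follow-up metric comparisons should also be Bonferroni
corrected is left to the caller (the per-model p-values are returned
unadjusted); the package corrects where the procedure prescribes it — across
the cluster distance tests.

# The synthetic cohort generator

`generate_cohort()` draws the four genotype groups (default sizes
83/11/34/16, i.e. 27 *APOE*+ and 50 *MAPT*+ of 144) with ages from a
truncated normal (mean 20.6, sd 0.9, range 18–24), integer education 12–14
(mean ≈ 12.4), sex ≈ 41 % male and TIV ~ N(1450, 110) ml, matching the
demographic structure of young-adult imaging-genetics cohorts.

`generate_features()` writes each feature as

baseline(region) + covariate terms + genotype main effects + interaction +
noise,

where the 68 regions belong to four fixed morphological archetypes
(medium/thick/smooth, large/thin/smooth, small/thick/convoluted,
medium/thin/convoluted — membership mirrored across hemispheres and chosen
so that temporal/insular/cingulate regions form the archetype-1 belt), each
region gets a fixed archetype-jittered baseline, and genotype effects are
standardized shifts in units of the per-metric residual sd. Defaults plant
what young-adult carriers show qualitatively: thinner, more convoluted
cortex in carriers of either allele (±0.25 sd for *APOE*, ±0.20 sd for
*MAPT*), plus a double-carrier-only +0.5 sd increase in curvature and
folding index confined to the archetype-1 regions. No published effect
magnitudes exist for this age range, so the sizes are conventions chosen
once: small enough that the mass-univariate scan fails FDR correction, large
enough that the multivariate classifier succeeds — the qualitative pattern
the method exists to exploit.

What the generator deliberately does **not** emulate: spatial covariance
between regions (noise is i.i.d. per feature; a correlation parameter was
considered and left out because no covariance information is available to
set it), measurement artefacts, site effects, non-Gaussian tails, and any
genotype structure beyond carrier flags (no Hardy–Weinberg machinery, no
dosage). Passing tests therefore demonstrate the *procedures* are correct
and calibrated — not that real cortical data would yield any particular
effect size.

# Problem sizes used in the checks

The package's own acceptance checks run, per invocation: worked-example
confusion arithmetic (instant); permutation calibration on 1000 balanced
global-null cohorts of n = 144 at 99 permutations each — the repeat count is
set so that the Monte-Carlo standard error of a rejection rate (~0.7
percentage points) is small against the ±2-point band being checked, and the
`dcd` engine exists so this finishes in minutes; GHSOM archetype recovery
over 20 seeds;
interaction power and family-wise error over 500 simulations each at group
sizes 83/11/34/16. The calibration cohort is balanced (36 per genotype
cell) because under the study's 27/117 imbalance a null classifier collapses
to the majority class and ties sensitivity, PPV and F at zero in both the
observed and permuted runs — no p-value can be uniform under point-mass
ties.

# Known limitations

* GHSOM hyperparameters are conventions; a different `tau1` changes the
  granularity of the top layer, and with real (less separated) data the
  recovered cluster count is sensitive to it.
* The interaction test at realistic group sizes (16 double carriers) has
  modest power (≈0.4 at a 1-sd plant under Bonferroni ×4) — detected effects
  at these sizes are expected to be coarse.
* The screening step keeps features at an uncorrected 5 % level inside each
  fold; under a global null the SVM then trains on ~14 noise features. This
  is by construction and is why significance claims rest on the permutation
  test, not on the screen.
* Region profiles cluster cohort means; individual-specific cluster
  structure (e.g. subject-level parcellation differences) is out of scope,
  as is anything vertex-wise.

# A worked run

```{r, eval = FALSE}
library(morphrisk)

coh <- generate_cohort(seed = 1)                 # 144 participants, 27/50 carriers
X   <- generate_features(coh, effect_config(seed = 2))

cv  <- cv_classify(X, coh$apoe_pos, coh[c("age", "sex", "education")], seed = 3)
cv$report                                        # pooled confusion + 7 metrics

wm  <- summarize_weights(cv$weights)
head(wm$region_importance)                       # most discriminative regions

zp  <- zscore_profiles(X)
g   <- train_ghsom(zp$profiles, seed = 4)
a   <- assign_regions(g, zp$profiles)            # 4 clusters on default data
D   <- intra_cluster_distances(a, zp$tensor)
interaction_glm(D, coh$apoe_pos, coh$mapt_pos,
                coh[c("age", "sex", "education")])$interaction
```
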