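#' Configuration of planted effects for the synthetic cohort generator
#'
#' Encodes the generative model behind [generate_features()]: per-region
#' archetype baselines, covariate slopes, standardized genotype main effects,
#' a gene-gene interaction restricted to a designated region subset, and
#' residual noise. Effects are expressed in residual-standard-deviation units
#' per metric, so `main_effect_apoe["thickness"] = -0.25` plants a 0.25-sd
#' thinning in carriers. Defaults reproduce the qualitative pattern reported
#' for young-adult risk carriers: thinner, more convoluted cortex in carriers
#' of either risk allele, plus a double-carrier-only increase in curvature
#' and folding index confined to the archetype-1 (medium-sized, thicker,
#' less convoluted) regions.
#'
#' @param baseline_profiles 4 x 4 matrix (archetype x area/thickness/
#'   curvature/folding_index) of archetype means, in native units
#'   (mm^2, mm, 1/mm, unitless).
#' @param covariate_slopes 3 x 5 matrix (age/sex/education x metric incl.
#'   volume) of covariate effects in native units; age and education are
#'   centered at 21 and 12.4 years before applying slopes.
#' @param main_effect_apoe,main_effect_mapt named length-5 numeric: per-metric
#'   standardized shift in carriers.
#' @param interaction_effect named length-5 numeric: additional standardized
#'   shift applied only to carriers of both risk alleles, only in
#'   `interaction_regions`.
#' @param interaction_regions character subset of the 68 cortical regions
#'   receiving the interaction; default: archetype-1 regions.
#' @param noise_sd named length-5 numeric, residual standard deviation per
#'   metric in native units (>= 0; 0 is a degenerate noiseless mode used in
#'   tests).
#' @param region_jitter_sd named length-4 numeric: SD of the fixed per-region
#'   offset around the archetype mean (gives the 68 regions distinct but
#'   archetype-clustered baselines).
#' @param subcortical_baselines named length-7 numeric, mean volumes (mm^3)
#'   for thalamus/caudate/putamen/pallidum/hippocampus/amygdala/accumbens.
#' @param tiv_slope volume change (mm^3) per ml of total intracranial volume
#'   deviation from 1450 ml.
#' @param seed integer seed driving region baselines and residual noise.
#' @return an object of class `effect_config` (a validated list).
#' @examples
#' cfg <- effect_config(seed = 1)
#' cfg$main_effect_apoe
#' @export
effect_config <- function(baseline_profiles = default_archetype_profiles(),
                          covariate_slopes = default_covariate_slopes(),
                          main_effect_apoe = c(area = 0, thickness = -0.25,
                                               curvature = 0.25,
                                               folding_index = 0.25,
                                               volume = 0),
                          main_effect_mapt = c(area = 0, thickness = -0.20,
                                               curvature = 0.20,
                                               folding_index = 0.20,
                                               volume = 0),
                          interaction_effect = c(area = 0, thickness = 0,
                                                 curvature = 0.5,
                                                 folding_index = 0.5,
                                                 volume = 0),
                          interaction_regions = NULL,
                          noise_sd = c(area = 180, thickness = 0.12,
                                       curvature = 0.008,
                                       folding_index = 0.06, volume = 120),
                          region_jitter_sd = c(area = 80, thickness = 0.05,
                                               curvature = 0.004,
                                               folding_index = 0.03),
                          subcortical_baselines = c(thalamus = 7500,
                                                    caudate = 3800,
                                                    putamen = 5200,
                                                    pallidum = 1800,
                                                    hippocampus = 4100,
                                                    amygdala = 1700,
                                                    accumbens = 650),
                          tiv_slope = 2.0,
                          seed = NULL) {
  metrics5 <- c(cortical_metrics(), "volume")
  need5 <- function(x, what) {
    if (is.null(names(x))) names(x) <- metrics5
    if (!all(metrics5 %in% names(x))) {
      stop(what, " must be named with: ", paste(metrics5, collapse = ", "))
    }
    x[metrics5]
  }
  if (is.null(interaction_regions)) {
    interaction_regions <- names(region_archetypes())[region_archetypes() == 1L]
  }
  unknown <- setdiff(interaction_regions, cortical_regions())
  if (length(interaction_regions) == 0L) {
    stop("interaction_regions must be non-empty")
  }
  if (length(unknown)) {
    stop("unknown region name(s) in interaction_regions: ",
         paste(unknown, collapse = ", "))
  }
  noise_sd <- need5(noise_sd, "noise_sd")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  cfg <- list(baseline_profiles = baseline_profiles,
              covariate_slopes = covariate_slopes,
              main_effect_apoe = need5(main_effect_apoe, "main_effect_apoe"),
              main_effect_mapt = need5(main_effect_mapt, "main_effect_mapt"),
              interaction_effect = need5(interaction_effect,
                                         "interaction_effect"),
              interaction_regions = interaction_regions,
              noise_sd = noise_sd,
              region_jitter_sd = region_jitter_sd[cortical_metrics()],
              subcortical_baselines = subcortical_baselines,
              tiv_slope = tiv_slope,
              seed = seed)
  structure(cfg, class = "effect_config")
}

#' @rdname effect_config
#' @export
default_archetype_profiles <- function() {
  m <- rbind(c(2500, 2.90, 0.105, 0.40),   # medium, thick, low convolution
             c(3800, 2.30, 0.110, 0.45),   # large, thin, low convolution
             c(1500, 2.90, 0.150, 0.85),   # small, thick, high convolution
             c(2500, 2.30, 0.145, 0.80))   # medium, thin, high convolution
  dimnames(m) <- list(paste0("archetype", 1:4), cortical_metrics())
  m
}

#' @rdname effect_config
#' @export
default_covariate_slopes <- function() {
  m <- rbind(age       = c(0,   -0.010, 0, 0, -5),
             sex       = c(120,  0,     0, 0, 200),
             education = c(0,    0.005, 0, 0, 0))
  colnames(m) <- c(cortical_metrics(), "volume")
  m
}

#' Generate a synthetic cohort with genotype groups and covariates
#'
#' Draws a cohort with the four-genotype-group structure used in
#' imaging-genetics studies of APOE e4 and MAPT rs242557 A: group sizes are
#' given in the order (APOE-/MAPT-, APOE+/MAPT-, APOE-/MAPT+, APOE+/MAPT+).
#' Ages come from a normal distribution (mean 20.6, sd 0.9) truncated to
#' `age_range`; education is integer-valued in 12-14 years; total
#' intracranial volume (TIV) is normal with mean 1450 ml, sd 110 ml.
#'
#' @param group_sizes integer length 4, participants per genotype group;
#'   default 83/11/34/16 (144 total; 27 APOE+ and 50 MAPT+).
#' @param age_range numeric length 2, inclusive age bounds in years.
#' @param seed integer seed; the same seed gives a bit-identical table.
#' @param p_male probability of sex = 1 (male).
#' @return a `cohort_table` data.frame with columns `participant_id`,
#'   `apoe_pos`, `mapt_pos`, `age`, `sex`, `education`, `tiv`.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' table(coh$apoe_pos, coh$mapt_pos)
#' @export
generate_cohort <- function(group_sizes = c(83, 11, 34, 16),
                            age_range = c(18, 24), seed = NULL,
                            p_male = 0.41) {
  if (length(group_sizes) != 4L || any(is.na(group_sizes))) {
    stop("group_sizes must be four counts")
  }
  if (any(group_sizes < 0)) stop("group_sizes must be non-negative")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("age_range must be an increasing pair")
  }
  n <- sum(group_sizes)
  apoe <- rep(c(0L, 1L, 0L, 1L), times = group_sizes)
  mapt <- rep(c(0L, 0L, 1L, 1L), times = group_sizes)
  with_seed(seed, {
    age <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {                # rejection-sample the truncation
      age[todo] <- stats::rnorm(length(todo), 20.6, 0.9)
      todo <- which(age < age_range[1] | age > age_range[2])
    }
    sex <- stats::rbinom(n, 1L, p_male)
    education <- sample(12:14, n, replace = TRUE, prob = c(0.65, 0.30, 0.05))
    tiv <- stats::rnorm(n, 1450, 110)
    out <- data.frame(participant_id = sprintf("sub-%04d", seq_len(n)),
                      apoe_pos = apoe, mapt_pos = mapt,
                      age = age, sex = sex, education = education, tiv = tiv,
                      stringsAsFactors = FALSE)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Generate a morphometric feature matrix for a cohort
#'
#' Builds the 286-column feature matrix (68 cortical regions x
#' area/thickness/curvature/folding_index + 14 subcortical volumes) as
#' archetype baseline + fixed per-region offset + covariate terms + genotype
#' main effects + interaction term (double carriers only, designated regions
#' only) + i.i.d. Gaussian noise. Genotype effects are standardized shifts
#' scaled by the per-metric residual sd. Subcortical volumes additionally
#' scale with TIV. Positivity of area, thickness and volume is enforced by
#' clamping at a tiny positive value (never triggered under default noise).
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param config an [effect_config()]; its `seed` drives both region
#'   baselines and residual noise, so identical cohort + config give a
#'   bit-identical matrix.
#' @return numeric matrix, participants x 286 named features (the
#'   FeatureMatrix container used throughout the package).
#' @examples
#' coh <- generate_cohort(c(5, 5, 5, 5), seed = 1)
#' X <- generate_features(coh, effect_config(seed = 2))
#' dim(X)
#' @export
generate_features <- function(cohort, config = effect_config()) {
  if (!inherits(cohort, "data.frame") || nrow(cohort) == 0L) {
    stop("cohort must be a non-empty cohort table")
  }
  req <- c("participant_id", "apoe_pos", "mapt_pos", "age", "sex",
           "education", "tiv")
  if (!all(req %in% names(cohort))) {
    stop("cohort lacks columns: ", paste(setdiff(req, names(cohort)),
                                         collapse = ", "))
  }
  if (!inherits(config, "effect_config")) stop("config must be an effect_config")
  n <- nrow(cohort)
  regions <- cortical_regions()
  arch <- region_archetypes()
  metrics <- cortical_metrics()
  age_c <- cohort$age - 21
  edu_c <- cohort$education - 12.4
  sex <- cohort$sex
  apoe <- cohort$apoe_pos
  mapt <- cohort$mapt_pos
  both <- apoe * mapt
  in_subset <- as.numeric(regions %in% config$interaction_regions)

  with_seed(config$seed, {
    jitter <- matrix(stats::rnorm(68 * 4), 68, 4,
                     dimnames = list(regions, metrics))
    jitter <- sweep(jitter, 2, config$region_jitter_sd, `*`)
    sub_names <- subcortical_structures()
    sub_base <- config$subcortical_baselines[sub("^(left|right)_", "",
                                                 sub_names)]
    sub_base <- sub_base + stats::rnorm(14, 0, 0.02 * sub_base)

    X <- matrix(NA_real_, n, 286,
                dimnames = list(cohort$participant_id, feature_names()))
    for (m in metrics) {
      b <- config$baseline_profiles[arch, m] + jitter[, m]
      covar <- age_c * config$covariate_slopes["age", m] +
        sex * config$covariate_slopes["sex", m] +
        edu_c * config$covariate_slopes["education", m]
      geno <- (apoe * config$main_effect_apoe[m] +
                 mapt * config$main_effect_mapt[m]) * config$noise_sd[m]
      inter <- both * config$interaction_effect[m] * config$noise_sd[m]
      noise <- matrix(stats::rnorm(n * 68, 0, config$noise_sd[m]), n, 68)
      vals <- outer(rep(1, n), b) + (covar + geno) +
        outer(inter, in_subset) + noise
      X[, paste(regions, m, sep = "_")] <- vals
    }
    covar_v <- age_c * config$covariate_slopes["age", "volume"] +
      sex * config$covariate_slopes["sex", "volume"] +
      edu_c * config$covariate_slopes["education", "volume"] +
      config$tiv_slope * (cohort$tiv - 1450)
    geno_v <- (apoe * config$main_effect_apoe["volume"] +
                 mapt * config$main_effect_mapt["volume"] +
                 both * config$interaction_effect["volume"]) *
      config$noise_sd["volume"]
    noise_v <- matrix(stats::rnorm(n * 14, 0, config$noise_sd["volume"]),
                      n, 14)
    X[, paste(sub_names, "volume", sep = "_")] <-
      outer(rep(1, n), sub_base) + (covar_v + geno_v) + noise_v

    pos_cols <- grep("_(area|thickness|volume)$", colnames(X))
    X[, pos_cols] <- pmax(X[, pos_cols], 1e-6)
    X
  })
}
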