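#' Desikan-Killiany cortical parcellation and subcortical structures
#'
#' Region naming used throughout the package. The cortex is parcellated into
#' 34 regions per hemisphere (68 total) following the Desikan-Killiany atlas;
#' 14 subcortical grey-matter structures (bilateral thalamus, caudate,
#' putamen, pallidum, hippocampus, amygdala, accumbens) carry a single volume
#' feature each. Canonical feature names are
#' `<hemi>_<region>_<metric>` with `hemi` in `left`/`right`, lowercase,
#' snake-case, e.g. `left_precuneus_thickness`. This naming makes weight maps
#' and cluster outputs joinable across modules.
#'
#' @return `dk_regions()`: character vector of the 34 base region labels.
#'   `cortical_regions()`: the 68 hemisphere-qualified region names.
#'   `subcortical_structures()`: the 14 hemisphere-qualified structure names.
#'   `feature_names()`: all 286 canonical feature names (68 regions x
#'   area/thickness/curvature/folding_index, then 14 volumes).
#' @examples
#' length(feature_names())  # 286
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' @rdname dk_regions
#' @export
cortical_regions <- function() {
  as.vector(t(outer(c("left", "right"), dk_regions(), paste, sep = "_")))
}

#' @rdname dk_regions
#' @export
subcortical_structures <- function() {
  base <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
            "amygdala", "accumbens")
  c(paste0("left_", base), paste0("right_", base))
}

#' Cortical metrics measured per region
#' @return character vector of the four cortical metric names.
#' @export
cortical_metrics <- function() {
  c("area", "thickness", "curvature", "folding_index")
}

#' @rdname dk_regions
#' @export
feature_names <- function() {
  cort <- as.vector(t(outer(cortical_regions(), cortical_metrics(),
                            paste, sep = "_")))
  c(cort, paste0(subcortical_structures(), "_volume"))
}

#' Split canonical feature names into hemisphere, region and metric
#'
#' @param x character vector of canonical feature names.
#' @return data.frame with columns `feature`, `hemi`, `region`
#'   (hemisphere-qualified), `metric`.
#' @examples
#' parse_feature_name("left_precuneus_thickness")
#' @export
parse_feature_name <- function(x) {
  known_metrics <- c(cortical_metrics(), "volume")
  metric <- rep(NA_character_, length(x))
  rest <- x
  for (m in known_metrics) {
    suf <- paste0("_", m)
    hit <- endsWith(x, suf) & is.na(metric)
    metric[hit] <- m
    rest[hit] <- substr(x[hit], 1L, nchar(x[hit]) - nchar(suf))
  }
  bad <- is.na(metric)
  if (any(bad)) {
    stop("unknown feature name(s): ", paste(x[bad], collapse = ", "))
  }
  hemi <- sub("_.*$", "", rest)
  if (!all(hemi %in% c("left", "right"))) {
    stop("feature names must start with 'left_' or 'right_': ",
         paste(x[!hemi %in% c("left", "right")], collapse = ", "))
  }
  valid_region <- rest %in% c(cortical_regions(), subcortical_structures())
  if (!all(valid_region)) {
    stop("unknown region in feature name(s): ",
         paste(x[!valid_region], collapse = ", "))
  }
  data.frame(feature = x, hemi = hemi, region = rest, metric = metric,
             stringsAsFactors = FALSE)
}

# Archetype membership for the 34 base regions. Four morphological
# archetypes mirror the profile classes recovered in young-adult cohorts:
#   1 medium area, thick, low convolution (temporal/insular/cingulate belt)
#   2 large area, thin, low convolution (dorsal association cortex)
#   3 small area, thick, high convolution (occipital/medial regions)
#   4 medium area, thin, high convolution (opercular/parietal regions)
region_archetype_map <- function() {
  a1 <- c("superiortemporal", "middletemporal", "inferiortemporal",
          "entorhinal", "parahippocampal", "temporalpole", "fusiform",
          "insula", "caudalmiddlefrontal", "lateralorbitofrontal",
          "parsorbitalis", "rostralanteriorcingulate",
          "caudalanteriorcingulate", "paracentral", "bankssts",
          "transversetemporal", "medialorbitofrontal")
  a2 <- c("superiorfrontal", "rostralmiddlefrontal", "superiorparietal",
          "inferiorparietal", "lateraloccipital", "precentral", "precuneus")
  a3 <- c("pericalcarine", "cuneus", "lingual", "isthmuscingulate",
          "posteriorcingulate", "frontalpole")
  a4 <- c("parsopercularis", "parstriangularis", "postcentral",
          "supramarginal")
  out <- integer(34)
  names(out) <- dk_regions()
  out[a1] <- 1L; out[a2] <- 2L; out[a3] <- 3L; out[a4] <- 4L
  out
}

#' Archetype membership of the 68 cortical regions
#'
#' The synthetic-data generator draws each region's baseline profile from one
#' of four morphological archetypes; membership is mirrored across
#' hemispheres. The planted gene-gene interaction defaults to archetype-1
#' regions (medium-sized, thicker, less convoluted temporal/insular belt).
#'
#' @return named integer vector (names = 68 hemisphere-qualified regions,
#'   values in 1..4).
#' @export
region_archetypes <- function() {
  base <- region_archetype_map()
  out <- base[sub("^(left|right)_", "", cortical_regions())]
  names(out) <- cortical_regions()
  out
}
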