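#' Curvature-derived cortical metrics
#'
#' Mean curvature and folding index from the two principal normal curvatures
#' of the cortical surface. With `k1` the maximum and `k2` the minimum normal
#' curvature (1/mm), mean curvature is `H = (k1 + k2) / 2` and the folding
#' index is `FI = |k1| * (|k1| - |k2|)`. The folding-index formula is applied
#' after ordering the pair by absolute magnitude (the FreeSurfer convention),
#' which guarantees `FI >= 0`; with a strict max/min ordering the raw formula
#' could go negative (e.g. k1 = 1, k2 = -2).
#'
#' @param k1,k2 numeric vectors of principal curvatures (recycled to common
#'   length); must be finite.
#' @return numeric vector: mean curvature `H`, or folding index `FI >= 0`.
#' @examples
#' mean_curvature(0.3, -0.1)  # 0.1
#' folding_index(2, 1)        # 2
#' folding_index(1, -2)       # 2, |k| ordering
#' @export
mean_curvature <- function(k1, k2) {
  stop_if_not_finite(c(k1, k2), "principal curvatures")
  (k1 + k2) / 2
}

#' @rdname mean_curvature
#' @export
folding_index <- function(k1, k2) {
  stop_if_not_finite(c(k1, k2), "principal curvatures")
  a <- pmax(abs(k1), abs(k2))
  b <- pmin(abs(k1), abs(k2))
  a * (a - b)
}

mandatory_cohort_cols <- c("participant_id", "apoe_pos", "mapt_pos", "age",
                           "sex", "education", "tiv")

#' Write a cohort and its feature matrix to a tab-separated file
#'
#' One row per participant: the seven cohort columns followed by the named
#' feature columns. Numbers are written with 17 significant digits so a
#' write/read cycle is bit-identical. If `config` is given, a sidecar YAML
#' file `<path>.yml` records every generation parameter and the seed.
#'
#' @param cohort a cohort table (see [generate_cohort()]).
#' @param features numeric matrix with rows matching `cohort` and named
#'   feature columns.
#' @param path output file path.
#' @param config optional [effect_config()] recorded alongside the data.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(cohort, features, path, config = NULL) {
  if (nrow(cohort) != nrow(features)) stop("cohort/features row mismatch")
  df <- cbind(cohort[mandatory_cohort_cols], as.data.frame(features))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$baseline_profiles <- as.data.frame(cfg$baseline_profiles)
    cfg$covariate_slopes <- as.data.frame(cfg$covariate_slopes)
    yaml::write_yaml(cfg, paste0(path, ".yml"))
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' Validates the mandatory cohort columns, 0/1 genotype flags, uniqueness of
#' participant ids, numeric cells, and strict positivity of area, thickness
#' and volume features; violations are rejected with row/column context.
#'
#' @param path tab-separated file with a header.
#' @return list with elements `cohort` (a `cohort_table`) and `features`
#'   (numeric matrix with participant-id rownames).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  missing <- setdiff(mandatory_cohort_cols, names(df))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$participant_id)) {
    dup <- df$participant_id[duplicated(df$participant_id)][1]
    stop("duplicate participant_id: ", dup)
  }
  numeric_cols <- setdiff(names(df), "participant_id")
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop("non-numeric cell in column '", cl, "', row ", bad[1],
           ": '", df[[cl]][bad[1]], "'")
    }
    df[[cl]] <- v
  }
  for (fl in c("apoe_pos", "mapt_pos")) {
    if (!all(df[[fl]] %in% c(0, 1))) {
      bad <- which(!df[[fl]] %in% c(0, 1))[1]
      stop("column '", fl, "' must be 0/1; row ", bad, " is ", df[[fl]][bad])
    }
  }
  feat_cols <- setdiff(names(df), mandatory_cohort_cols)
  features <- as.matrix(df[feat_cols])
  rownames(features) <- df$participant_id
  pos_cols <- grep("_(area|thickness|volume)$", colnames(features),
                   value = TRUE)
  for (cl in pos_cols) {
    bad <- which(features[, cl] <= 0)
    if (length(bad)) {
      stop("non-positive value in column '", cl, "', row ", bad[1],
           " (", df$participant_id[bad[1]], "): ", features[bad[1], cl])
    }
  }
  cohort <- df[mandatory_cohort_cols]
  class(cohort) <- c("cohort_table", "data.frame")
  list(cohort = cohort, features = features)
}

# Parse one FreeSurfer-dialect stats file: '#' comment header with a
# '# ColHeaders ...' line, whitespace-delimited data rows.
read_fs_stats_file <- function(path, needed) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ch <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(ch) != 1L) {
    stop("no '# ColHeaders' line in ", path, "; truncated or not a stats file")
  }
  headers <- strsplit(sub("^# ColHeaders\\s+", "", ch), "\\s+")[[1]]
  miss <- setdiff(needed, headers)
  if (length(miss)) {
    stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(data_lines)) stop("no data rows in ", path)
  fields <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(headers))) {
    stop("row ", which(nf != length(headers))[1], " of ", path,
         " has ", nf[nf != length(headers)][1], " fields, expected ",
         length(headers), " (truncated file?)")
  }
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- headers
  for (cl in setdiff(needed, "StructName")) {
    out[[cl]] <- as.numeric(out[[cl]])
    if (anyNA(out[[cl]])) stop("non-numeric ", cl, " in ", path)
  }
  out
}

aseg_name_map <- function() {
  base <- c("Thalamus-Proper" = "thalamus", "Thalamus" = "thalamus",
            "Caudate" = "caudate", "Putamen" = "putamen",
            "Pallidum" = "pallidum", "Hippocampus" = "hippocampus",
            "Amygdala" = "amygdala", "Accumbens-area" = "accumbens",
            "Accumbens" = "accumbens")
  out <- c(stats::setNames(paste0("left_", base), paste0("Left-", names(base))),
           stats::setNames(paste0("right_", base), paste0("Right-", names(base))))
  out
}

#' Read FreeSurfer regional stats files into one feature record
#'
#' Parses per-hemisphere `aparc.stats` tables (columns `StructName`,
#' `SurfArea`, `ThickAvg`, `MeanCurv`, `FoldInd`) and an `aseg.stats` table
#' (`StructName`, `Volume_mm3`), and assembles the canonical 68 x 4 cortical
#' + 14 subcortical feature vector for one participant. Every atlas region
#' must be present exactly once; unknown structure names are rejected.
#'
#' @param aparc_lh,aparc_rh paths to left/right hemisphere aparc stats files.
#' @param aseg path to the aseg stats file; subcortical rows other than the
#'   14 configured structures are ignored.
#' @return named numeric vector of 286 features in canonical order.
#' @export
read_freesurfer_stats <- function(aparc_lh, aparc_rh, aseg) {
  needed <- c("StructName", "SurfArea", "ThickAvg", "MeanCurv", "FoldInd")
  out <- stats::setNames(rep(NA_real_, 286), feature_names())
  for (hemi in c("left", "right")) {
    path <- if (hemi == "left") aparc_lh else aparc_rh
    tab <- read_fs_stats_file(path, needed)
    unknown <- setdiff(tab$StructName, dk_regions())
    if (length(unknown)) {
      stop("unknown StructName in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    miss <- setdiff(dk_regions(), tab$StructName)
    if (length(miss)) {
      stop(path, " is missing atlas region(s): ", paste(miss, collapse = ", "))
    }
    pre <- paste0(hemi, "_", tab$StructName)
    out[paste0(pre, "_area")] <- tab$SurfArea
    out[paste0(pre, "_thickness")] <- tab$ThickAvg
    out[paste0(pre, "_curvature")] <- tab$MeanCurv
    out[paste0(pre, "_folding_index")] <- tab$FoldInd
  }
  atab <- read_fs_stats_file(aseg, c("StructName", "Volume_mm3"))
  map <- aseg_name_map()
  known <- atab$StructName %in% names(map)
  feats <- map[atab$StructName[known]]
  dup <- duplicated(feats)
  if (any(dup)) stop("duplicate aseg structure: ", feats[dup][1])
  out[paste0(feats, "_volume")] <- atab$Volume_mm3[known]
  vol_missing <- names(out)[is.na(out)]
  if (length(vol_missing)) {
    stop(aseg, " is missing structure(s) for: ",
         paste(vol_missing, collapse = ", "))
  }
  out
}
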