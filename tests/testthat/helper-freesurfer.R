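# Writers producing FreeSurfer-dialect stats files for reader tests; values
# are fabricated, the dialect (comment header + ColHeaders + whitespace
# table) follows the aparc.stats / aseg.stats layout.

write_fs_aparc <- function(path, region_table) {
  lines <- c("# Table of FreeSurfer cortical parcellation statistics",
             "# anatomy_type surface",
             paste("# ColHeaders StructName NumVert SurfArea GrayVol",
                   "ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd"))
  rows <- sprintf("%s %d %.1f %.1f %.3f %.3f %.3f %.3f %.3f %.1f",
                  region_table$StructName, 1000L, region_table$SurfArea,
                  3000, region_table$ThickAvg, 0.5, region_table$MeanCurv,
                  0.03, region_table$FoldInd, 1.5)
  writeLines(c(lines, rows), path)
  path
}

write_fs_aseg <- function(path, struct_names, volumes) {
  lines <- c("# Title Segmentation Statistics",
             "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean")
  rows <- sprintf("%d %d %d %.1f %s %.2f", seq_along(struct_names),
                  10L + seq_along(struct_names), 5000L, volumes,
                  struct_names, 80)
  writeLines(c(lines, rows), path)
  path
}

full_aparc_table <- function(seed, base_area = 2500) {
  set.seed(seed)
  data.frame(StructName = dk_regions(),
             SurfArea = round(runif(34, 800, 4500), 1),
             ThickAvg = round(runif(34, 2, 3.2), 3),
             MeanCurv = round(runif(34, 0.09, 0.17), 3),
             FoldInd = round(runif(34, 0.2, 1.2), 3),
             stringsAsFactors = FALSE)
}

aseg_struct_names <- function() {
  base <- c("Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
            "Hippocampus", "Amygdala", "Accumbens-area")
  c(paste0("Left-", base), paste0("Right-", base))
}
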