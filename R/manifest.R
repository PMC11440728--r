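.histogram_feature_names <- c(
  "mean", "sd", "variance", "skewness", "kurtosis", "median", "min", "max",
  "range", "iqr", "energy", "entropy", "p10", "p90")

.glcm_feature_names <- c(
  "autocorrelation", "contrast", "correlation", "cluster_shade",
  "cluster_prominence", "cluster_tendency", "dissimilarity", "energy",
  "entropy", "homogeneity", "inverse_difference", "inverse_variance",
  "imc1", "imc2", "joint_average", "joint_variance", "max_probability",
  "sum_average", "sum_entropy", "sum_variance", "difference_entropy",
  "difference_variance")

.glrlm_feature_names <- c(
  "sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge", "srhge",
  "lrlge", "lrhge")

.lbp_feature_names <- c(paste0("bin_", sprintf("%02d", 1:16)), "entropy")

.geometry_feature_names <- c(
  "volume_mm3", "surface_area_mm2", "surface_to_volume",
  "max_diameter_3d_mm", "extent_x_mm", "extent_y_mm", "extent_z_mm",
  "equivalent_diameter_mm", "sphericity", "compactness",
  "spherical_disproportion", "major_axis_mm", "minor_axis_mm",
  "least_axis_mm", "elongation", "flatness", "bbox_fill_fraction")

.image_set_labels <- c("original", "LLL", "LLH", "LHL", "LHH", "HLL",
                       "HLH", "HHL", "HHH")

#' The intratumoral feature manifest
#'
#' The fixed, ordered list of the 593 intratumoral radiomic features:
#' for each of the 9 image sets (original volume + 8 stationary-wavelet
#' subbands) 14 histogram, 22 GLCM, 11 GLRLM and 17 local-binary-pattern
#' features (9 x 64 = 576), plus 17 mask-only geometry features.
#'
#' @return a data.frame with columns `name` (unique), `family` (one of
#'   histogram, glcm, glrlm, lbp, geometry) and `image_set` (original,
#'   LLL...HHH, or `n/a` for geometry).
#' @examples
#' m <- intratumoralManifest()
#' nrow(m)          # 593
#' table(m$family)
#' @export
intratumoralManifest <- function() {
  rows <- list()
  fams <- list(histogram = .histogram_feature_names,
               glcm = .glcm_feature_names,
               glrlm = .glrlm_feature_names,
               lbp = .lbp_feature_names)
  for (set in .image_set_labels)
    for (fam in names(fams))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(set, fam, fams[[fam]], sep = "_"),
        family = fam, image_set = set)
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste("geometry", .geometry_feature_names, sep = "_"),
    family = "geometry", image_set = "n/a")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 593L, !anyDuplicated(out$name))
  out
}

#' The peritumoral-vasculature feature manifest
#'
#' The fixed, ordered list of the 91 vasculature features: a morphology
#' block of 61 (five summary statistics -- mean, SD, skewness, kurtosis,
#' median -- over branches of 12 per-branch geometric quantities, plus
#' total vessel volume) and an organization block of 30 (5 count/density
#' features plus the same five summary statistics over 5 inter-branch
#' arrangement quantities).
#'
#' @return a data.frame with columns `name` and `block` (morphology /
#'   organization).
#' @examples
#' table(vesselManifest()$block)
#' @export
vesselManifest <- function() {
  stats5 <- c("mean", "sd", "skewness", "kurtosis", "median")
  morph_quant <- c("mean_curvature", "max_curvature", "mean_torsion",
                   "max_torsion", "length", "mean_radius", "straightness",
                   "curvature_skewness", "torsion_skewness",
                   "inflection_count", "total_curvature", "total_torsion")
  org_quant <- c("nearest_branch_distance", "orientation_angle",
                 "orientation_dispersion", "tumor_surface_distance",
                 "local_spacing")
  morph <- c(as.vector(t(outer(morph_quant, stats5, paste, sep = "_"))),
             "total_vessel_volume_mm3")
  org <- c("branch_count", "junction_count", "branch_density_cm3",
           "junction_density_cm3", "tip_count",
           as.vector(t(outer(org_quant, stats5, paste, sep = "_"))))
  out <- data.frame(
    name = c(paste0("morph_", morph), paste0("org_", org)),
    block = c(rep("morphology", length(morph)),
              rep("organization", length(org))))
  stopifnot(nrow(out) == 91L, sum(out$block == "morphology") == 61L,
            !anyDuplicated(out$name))
  out
}

#' Write a feature manifest as JSON
#'
#' @param manifest a manifest data.frame ([intratumoralManifest()] or
#'   [vesselManifest()]).
#' @param path output file path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows")
  invisible(path)
}
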