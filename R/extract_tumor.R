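#' Extract the 593 intratumoral radiomic features
#'
#' Runs the full intratumoral pipeline on a (resampled, standardized)
#' volume: a single-level stationary Haar decomposition produces 8
#' subbands; histogram (14), GLCM (22), GLRLM (11) and LBP (17) features
#' are computed inside the tumor ROI on the original volume and every
#' subband (9 x 64 = 576), and 17 mask-only geometry features complete
#' the vector. Output order and names follow [intratumoralManifest()].
#'
#' @param volume an [ImageVolume-class] (typically after
#'   [resampleIsotropic()] and [zscoreStandardize()]).
#' @param tumor_mask a [RoiMask-class] aligned to `volume`, nonempty.
#' @param n_bins texture quantization levels (default 64).
#' @return named numeric vector of length 593.
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(grid_shape = c(32, 32, 32), seed = 1))
#' fv <- extractIntratumoral(zscoreStandardize(ph$volume), ph$tumor)
#' length(fv)
#' }
#' @export
extractIntratumoral <- function(volume, tumor_mask, n_bins = 64L) {
  stopifnot(is(volume, "ImageVolume"), is(tumor_mask, "RoiMask"))
  if (!identical(dim(volume@values), dim(tumor_mask@values)))
    stop("volume and mask dimensions differ")
  if (!any(tumor_mask@values)) stop("empty tumor mask")
  # crop to the mask bounding box (with margin for LBP neighborhoods and
  # wavelet support) to keep the decomposition cheap
  d <- dim(volume@values)
  idx <- which(tumor_mask@values, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2, max) + 2L, d)
  v <- volume@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- tumor_mask@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                         drop = FALSE]
  sub <- imageVolume(v, spacing = volume@spacing)
  ws <- waveletDecompose(sub)
  sets <- c(list(original = sub), ws@subbands)
  out <- numeric(0)
  for (set_name in .image_set_labels) {
    arr <- sets[[set_name]]@values
    hist_f <- histogramFeatures(arr, m, n_bins)
    glcm_f <- glcmFeatures(arr, m, n_bins)
    glrlm_f <- glrlmFeatures(arr, m, n_bins)
    lbp_f <- lbpFeatures(arr, m)
    block <- c(hist_f, glcm_f, glrlm_f, lbp_f)
    names(block) <- paste(set_name,
                          c(paste0("histogram_", .histogram_feature_names),
                            paste0("glcm_", .glcm_feature_names),
                            paste0("glrlm_", .glrlm_feature_names),
                            paste0("lbp_", .lbp_feature_names)),
                          sep = "_")
    out <- c(out, block)
  }
  geom <- geometryFeatures(tumor_mask)
  names(geom) <- paste0("geometry_", .geometry_feature_names)
  out <- c(out, geom)
  manifest <- intratumoralManifest()
  stopifnot(identical(names(out), manifest$name))
  out
}
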