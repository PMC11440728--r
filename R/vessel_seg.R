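#' Threshold-based lung mask fallback
#'
#' Labels low-intensity connected components as lung when no external
#' lung segmentation is supplied: voxels below the volume's Otsu
#' threshold are grouped into 26-connected components, components smaller
#' than `min_fraction` of the volume are dropped, internal holes (vessels,
#' nodules) are filled, and the tumor region is re-included by union when
#' a tumor mask is given.
#'
#' @param volume an [ImageVolume-class] (standardized intensities).
#' @param tumor_mask optional [RoiMask-class] unioned into the result.
#' @param min_fraction minimum component size as a fraction of the volume
#'   (default 0.01).
#' @return a [RoiMask-class].
#' @export
lungMaskFallback <- function(volume, tumor_mask = NULL,
                             min_fraction = 0.01) {
  stopifnot(is(volume, "ImageVolume"))
  v <- volume@values
  thr <- otsuThreshold(as.vector(v))
  low <- v <= thr
  if (!any(low)) stop("no lung-like low-intensity component found")
  lab <- .label_components(low, 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_fraction * length(v))
  if (length(keep) == 0)
    stop("no lung-like low-intensity component found")
  lung <- array(lab %in% keep, dim(v))
  lung <- .fill_holes(lung)
  if (!is.null(tumor_mask)) lung <- lung | tumor_mask@values
  roiMask(lung, spacing = volume@spacing, origin = volume@origin)
}

.label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  array(lab, d)
}

# fill cavities: background components not touching the volume border
.fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- .label_components(bg, 6L)
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                            lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  holes <- bg & !(lab %in% border_labels)
  mask | array(holes, d)
}

#' Morphological cleanup of a binary vessel mask
#'
#' Binary opening with a ball structuring element (via the Euclidean
#' distance transform) followed by removal of 26-connected components
#' smaller than a minimum voxel count. An empty result is allowed and
#' flagged with attribute `empty`.
#'
#' @param mask a [RoiMask-class].
#' @param min_component_voxels minimum component size kept (default 27).
#' @param opening_radius_mm ball radius for the opening (default 1 mm;
#'   0 skips the opening).
#' @return a cleaned [RoiMask-class]; attribute `empty` is TRUE when
#'   nothing remains.
#' @export
morphologicalCleanup <- function(mask, min_component_voxels = 27L,
                                 opening_radius_mm = 1) {
  stopifnot(is(mask, "RoiMask"))
  m <- mask@values
  sp <- mask@spacing
  if (opening_radius_mm > 0 && any(m)) {
    r <- opening_radius_mm
    # erosion: keep voxels at distance > r from the background, then
    # dilation: voxels within r of the eroded set
    d2 <- .edt_sq(m, sp)
    eroded <- d2 > r^2
    if (any(eroded)) {
      d2b <- .edt_sq(!eroded, sp)
      m <- d2b <= r^2
    } else {
      m <- eroded
    }
  }
  if (any(m)) {
    lab <- .label_components(m, 26L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_voxels)
    m <- array(lab %in% keep, dim(m))
  }
  out <- roiMask(m, spacing = sp, origin = mask@origin)
  attr(out, "empty") <- !any(m)
  out
}

# squared Euclidean distance from in-mask voxels to the nearest
# background voxel (0 outside the mask)
.edt_sq <- function(mask, spacing) {
  d <- dim(mask)
  out <- cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(out, d)
}

#' Peritumoral cube bounds
#'
#' The axis-aligned bounding box of the tumor extended by a fixed margin
#' (default 25 mm, i.e. a 2.5-cm extension) on each side along each axis,
#' clipped to the image bounds.
#'
#' @param tumor_mask a nonempty [RoiMask-class].
#' @param extension_mm margin per side in mm (default 25).
#' @return a list with `lo` and `hi` (integer voxel indices, 1-based,
#'   inclusive) and `mask` (a [RoiMask-class] covering the cube).
#' @export
peritumoralCube <- function(tumor_mask, extension_mm = 25) {
  stopifnot(is(tumor_mask, "RoiMask"))
  m <- tumor_mask@values
  if (!any(m)) stop("empty tumor mask")
  d <- dim(m)
  sp <- tumor_mask@spacing
  idx <- which(m, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  ext_vox <- ceiling(extension_mm / sp)
  lo <- pmax(lo - ext_vox, 1L)
  hi <- pmin(hi + ext_vox, d)
  cube <- array(FALSE, d)
  cube[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  list(lo = as.integer(lo), hi = as.integer(hi),
       mask = roiMask(cube, spacing = sp, origin = tumor_mask@origin))
}

#' Segment peritumoral vasculature
#'
#' The full vessel-segmentation chain: multi-scale vesselness over the
#' lung, Otsu thresholding of the in-lung response, morphological
#' cleanup, and restriction to the peritumoral cube excluding the tumor
#' itself.
#'
#' @param volume an [ImageVolume-class] (resampled, standardized).
#' @param tumor_mask a nonempty [RoiMask-class].
#' @param lung_mask optional [RoiMask-class]; when NULL,
#'   [lungMaskFallback()] is used.
#' @param scales_mm vesselness scales (default `c(1, 1.5, 2, 3)`).
#' @param extension_mm peritumoral-cube margin (default 25).
#' @param min_component_voxels,opening_radius_mm cleanup parameters.
#' @return a list with `vessel_mask` ([RoiMask-class]), `cube` (bounds as
#'   from [peritumoralCube()]), `response` (vesselness volume) and
#'   `lung_mask`.
#' @export
segmentVessels <- function(volume, tumor_mask, lung_mask = NULL,
                           scales_mm = c(1, 1.5, 2, 3),
                           extension_mm = 25,
                           min_component_voxels = 27L,
                           opening_radius_mm = 1) {
  stopifnot(is(volume, "ImageVolume"), is(tumor_mask, "RoiMask"))
  if (is.null(lung_mask))
    lung_mask <- lungMaskFallback(volume, tumor_mask)
  resp <- vesselness(volume, scales_mm)
  inlung <- resp@values[lung_mask@values & !tumor_mask@values]
  thr <- tryCatch(otsuThreshold(inlung), error = function(e) Inf)
  vmask <- resp@values > thr & lung_mask@values & !tumor_mask@values
  vmask_roi <- roiMask(vmask, spacing = volume@spacing,
                       origin = volume@origin)
  cleaned <- morphologicalCleanup(vmask_roi, min_component_voxels,
                                  opening_radius_mm)
  cube <- peritumoralCube(tumor_mask, extension_mm)
  final <- cleaned@values & cube$mask@values & !tumor_mask@values
  list(vessel_mask = roiMask(final, spacing = volume@spacing,
                             origin = volume@origin),
       cube = cube, response = resp, lung_mask = lung_mask)
}
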