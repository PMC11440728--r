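#' Resample a volume or mask to isotropic voxels
#'
#' Resamples onto an isotropic grid (default 1 mm), the standard
#' preprocessing resolution for CT radiomics. Intensities are interpolated
#' trilinearly; masks use nearest-neighbor interpolation so that binary
#' topology is preserved. The output grid spans the same physical extent
#' (grid-point convention: voxel i sits at origin + i * spacing), so the
#' extent is preserved to within one voxel per axis.
#'
#' @param x an [ImageVolume-class] or [RoiMask-class].
#' @param target_mm positive scalar, target voxel size in mm (default 1).
#' @return an object of the same class as `x` with spacing
#'   `c(target_mm, target_mm, target_mm)`.
#' @examples
#' v <- imageVolume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
#'                  spacing = c(0.7, 0.7, 5))
#' imgSpacing(resampleIsotropic(v))
#' @export
resampleIsotropic <- function(x, target_mm = 1.0) {
  if (!is.numeric(target_mm) || length(target_mm) != 1 || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  is_mask <- is(x, "RoiMask")
  if (!is_mask && !is(x, "ImageVolume"))
    stop("x must be an ImageVolume or RoiMask")
  vals <- if (is_mask) array(as.numeric(x@values), dim(x@values)) else x@values
  sp <- x@spacing
  d <- dim(vals)
  # output grid: j * target covers [0, (n-1) * spacing] per axis
  nd <- pmax(2L, as.integer(floor((d - 1) * sp / target_mm + 1e-9)) + 1L)
  # fractional input coordinates (0-based) of each output sample
  cx <- (seq_len(nd[1]) - 1) * target_mm / sp[1]
  cy <- (seq_len(nd[2]) - 1) * target_mm / sp[2]
  cz <- (seq_len(nd[3]) - 1) * target_mm / sp[3]
  out <- if (is_mask) .interp_nearest(vals, cx, cy, cz)
         else .interp_trilinear(vals, cx, cy, cz)
  if (is_mask)
    roiMask(out != 0, spacing = rep(target_mm, 3), origin = x@origin)
  else
    imageVolume(out, spacing = rep(target_mm, 3), origin = x@origin)
}

.interp_trilinear <- function(vals, cx, cy, cz) {
  d <- dim(vals)
  x0 <- pmin(pmax(floor(cx), 0), d[1] - 2); fx <- cx - x0
  y0 <- pmin(pmax(floor(cy), 0), d[2] - 2); fy <- cy - y0
  z0 <- pmin(pmax(floor(cz), 0), d[3] - 2); fz <- cz - z0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  nd <- c(length(cx), length(cy), length(cz))
  X0 <- array(rep(x0, times = nd[2] * nd[3]), nd)
  Y0 <- array(rep(rep(y0, each = nd[1]), times = nd[3]), nd)
  Z0 <- array(rep(z0, each = nd[1] * nd[2]), nd)
  FX <- array(rep(fx, times = nd[2] * nd[3]), nd)
  FY <- array(rep(rep(fy, each = nd[1]), times = nd[3]), nd)
  FZ <- array(rep(fz, each = nd[1] * nd[2]), nd)
  at <- function(ix, iy, iz)
    vals[cbind(as.vector(ix) + 1L, as.vector(iy) + 1L, as.vector(iz) + 1L)]
  c000 <- at(X0, Y0, Z0);       c100 <- at(X0 + 1, Y0, Z0)
  c010 <- at(X0, Y0 + 1, Z0);   c110 <- at(X0 + 1, Y0 + 1, Z0)
  c001 <- at(X0, Y0, Z0 + 1);   c101 <- at(X0 + 1, Y0, Z0 + 1)
  c011 <- at(X0, Y0 + 1, Z0 + 1); c111 <- at(X0 + 1, Y0 + 1, Z0 + 1)
  fx <- as.vector(FX); fy <- as.vector(FY); fz <- as.vector(FZ)
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * c000 + fx * c100) +
                   fy * ((1 - fx) * c010 + fx * c110)) +
       fz * ((1 - fy) * ((1 - fx) * c001 + fx * c101) +
             fy * ((1 - fx) * c011 + fx * c111))
  array(v, nd)
}

.interp_nearest <- function(vals, cx, cy, cz) {
  d <- dim(vals)
  ix <- pmin(pmax(round(cx), 0), d[1] - 1) + 1L
  iy <- pmin(pmax(round(cy), 0), d[2] - 1) + 1L
  iz <- pmin(pmax(round(cz), 0), d[3] - 1) + 1L
  nd <- c(length(cx), length(cy), length(cz))
  IX <- rep(ix, times = nd[2] * nd[3])
  IY <- rep(rep(iy, each = nd[1]), times = nd[3])
  IZ <- rep(iz, each = nd[1] * nd[2])
  array(vals[cbind(IX, IY, IZ)], nd)
}

#' Z-score intensity standardization
#'
#' Standardizes a volume to zero mean and unit standard deviation over all
#' voxels, the conventional intensity normalization before texture
#' extraction when absolute units are not comparable across scanners.
#'
#' @param volume an [ImageVolume-class] with at least two distinct values.
#' @return an [ImageVolume-class] with mean 0 and SD 1.
#' @export
zscoreStandardize <- function(volume) {
  stopifnot(is(volume, "ImageVolume"))
  v <- volume@values
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate intensity: volume has zero variance")
  imageVolume((v - mean(v)) / s, spacing = volume@spacing,
              origin = volume@origin)
}
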