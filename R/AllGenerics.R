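#' Accessors for image-like objects
#'
#' `imgValues()`, `imgSpacing()` and `imgOrigin()` return the voxel array,
#' the per-axis voxel size (mm) and the physical origin (mm) of an
#' [ImageVolume-class] or [RoiMask-class].
#'
#' @param x an `ImageVolume` or `RoiMask`.
#' @return `imgValues()`: a 3D array; `imgSpacing()`, `imgOrigin()`:
#'   numeric(3).
#' @export
setGeneric("imgValues", function(x) standardGeneric("imgValues"))

#' @rdname imgValues
#' @export
setGeneric("imgSpacing", function(x) standardGeneric("imgSpacing"))

#' @rdname imgValues
#' @export
setGeneric("imgOrigin", function(x) standardGeneric("imgOrigin"))

#' @rdname imgValues
#' @export
setMethod("imgValues", "ImageVolume", function(x) x@values)
#' @rdname imgValues
#' @export
setMethod("imgValues", "RoiMask", function(x) x@values)
#' @rdname imgValues
#' @export
setMethod("imgSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname imgValues
#' @export
setMethod("imgSpacing", "RoiMask", function(x) x@spacing)
#' @rdname imgValues
#' @export
setMethod("imgOrigin", "ImageVolume", function(x) x@origin)
#' @rdname imgValues
#' @export
setMethod("imgOrigin", "RoiMask", function(x) x@origin)

#' Accessors for vessel trees
#'
#' @param x a [VesselTree-class].
#' @return `branches()`: list of n-by-3 coordinate matrices;
#'   `branchRadii()`: list of numeric radius vectors (mm); `junctions()`:
#'   m-by-3 matrix of junction coordinates.
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))
#' @rdname branches
#' @export
setGeneric("branchRadii", function(x) standardGeneric("branchRadii"))
#' @rdname branches
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
#' @rdname branches
#' @export
setMethod("branches", "VesselTree", function(x) x@branches)
#' @rdname branches
#' @export
setMethod("branchRadii", "VesselTree", function(x) x@radii)
#' @rdname branches
#' @export
setMethod("junctions", "VesselTree", function(x) x@junctions)

#' Evaluate a survival curve at given times
#'
#' Right-continuous step-function evaluation of S(t).
#'
#' @param curve a [SurvivalCurve-class].
#' @param times numeric vector of times (months), all >= 0.
#' @return numeric vector of survival probabilities.
#' @export
survivalAt <- function(curve, times) {
  stopifnot(is(curve, "SurvivalCurve"), all(times >= 0))
  idx <- findInterval(times, curve@time)
  curve@surv[pmax(idx, 1L)]
}

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume %d x %d x %d, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiMask %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "WaveletSet", function(object) {
  d <- dim(object@original@values)
  cat(sprintf("WaveletSet: original %d x %d x %d + 8 subbands (%s)\n",
              d[1], d[2], d[3], paste(names(object@subbands), collapse = " ")))
})

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree: %d branches, %d junctions, %d centerline points\n",
              length(object@branches), nrow(object@junctions),
              sum(vapply(object@branches, nrow, 1L))))
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve over [0, %.3g] months, %d steps, S(end) = %.3f\n",
              max(object@time), length(object@time),
              object@surv[length(object@surv)]))
})

setMethod("show", "SurvivalNetworkFit", function(object) {
  widths <- object@spec$hidden
  cat(sprintf(
    "SurvivalNetworkFit: input %d -> [%s] -> 1 (%s), %d epochs\n",
    object@spec$input_dim,
    if (length(widths)) paste(widths, collapse = ", ") else "linear",
    object@spec$activation, object@log$epochs %||% NA_integer_))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an ImageVolume
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3), voxel size in mm (default 1 mm isotropic).
#' @param origin numeric(3), physical origin in mm (default 0).
#' @return an [ImageVolume-class].
#' @examples
#' v <- imageVolume(array(rnorm(8^3), c(8, 8, 8)))
#' imgSpacing(v)
#' @export
imageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a RoiMask
#'
#' @param values 3D logical (or coercible) array.
#' @param spacing numeric(3), voxel size in mm.
#' @param origin numeric(3), physical origin in mm.
#' @return a [RoiMask-class].
#' @export
roiMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(as.logical(values), dim(values))
  new("RoiMask", values = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}
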