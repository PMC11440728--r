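#' @useDynLib periSurv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats approx chisq.test coef dnorm median na.omit pchisq
#'   pnorm quantile rbinom rexp rnorm runif sd setNames t.test uniroot var
#' @importFrom utils head tail
NULL

#' 3D image volume with physical geometry
#'
#' A scalar 3D grid together with its voxel spacing (mm) and physical
#' origin. Intensities are in arbitrary or standardized units.
#'
#' @slot values 3D numeric array (column-major x, y, z).
#' @slot spacing numeric(3), strictly positive voxel size in mm per axis.
#' @slot origin numeric(3), physical coordinate (mm) of the first voxel.
#'
#' @seealso [imageVolume()], [readVolume()], [resampleIsotropic()]
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite numbers")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Binary region-of-interest mask
#'
#' A logical 3D grid aligned to an [ImageVolume-class] (tumor, lung,
#' vessel, or peritumoral-cube mask).
#'
#' @slot values 3D logical array.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot origin numeric(3), physical origin in mm.
#'
#' @export
setClass("RoiMask",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (!is.logical(object@values))
      msg <- c(msg, "values must be logical")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (length(msg)) msg else TRUE
  }
)

#' Single-level stationary wavelet decomposition of a volume
#'
#' Holds the original volume and the eight same-shape subbands produced by
#' applying a low-pass (L) or high-pass (H) filter along each axis.
#'
#' @slot original the input [ImageVolume-class].
#' @slot subbands named list of exactly eight `ImageVolume` objects with
#'   labels LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#'
#' @seealso [waveletDecompose()]
#' @export
setClass("WaveletSet",
  representation(original = "ImageVolume", subbands = "list"),
  validity = function(object) {
    labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
    msg <- character()
    if (!identical(sort(names(object@subbands)), sort(labels)))
      msg <- c(msg, "subbands must be named exactly LLL...HHH")
    dims <- dim(object@original@values)
    for (nm in names(object@subbands)) {
      sb <- object@subbands[[nm]]
      if (!is(sb, "ImageVolume")) {
        msg <- c(msg, "each subband must be an ImageVolume"); break
      }
      if (!identical(dim(sb@values), dims))
        msg <- c(msg, sprintf("subband %s shape differs from original", nm))
      if (!isTRUE(all.equal(sb@spacing, object@original@spacing)))
        msg <- c(msg, sprintf("subband %s spacing differs", nm))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Vessel centerline tree
#'
#' Centerline point sequences grouped into branches, with junction
#' positions and a per-point radius estimate (distance to the vessel
#' surface).
#'
#' @slot branches list of n-by-3 numeric matrices of mm coordinates, each
#'   with at least 2 points and consecutive points at most 2 mm apart.
#' @slot radii list of numeric vectors, one radius (mm) per branch point.
#' @slot junctions m-by-3 matrix of junction coordinates (mm).
#' @slot bounds 2-by-3 matrix, physical bounds (mm) of the source cube.
#'
#' @seealso [extractCenterlines()], [branchGeometry()]
#' @export
setClass("VesselTree",
  representation(branches = "list", radii = "list", junctions = "matrix",
                 bounds = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@branches) != length(object@radii))
      msg <- c(msg, "branches and radii must have equal length")
    for (b in object@branches) {
      if (!is.matrix(b) || ncol(b) != 3L || nrow(b) < 2L) {
        msg <- c(msg, "each branch needs >= 2 points with 3 coordinates")
        break
      }
      steps <- sqrt(rowSums(diff(b)^2))
      if (any(steps > 2 + 1e-9)) {
        msg <- c(msg, "consecutive branch points must be <= 2 mm apart")
        break
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Survival curve
#'
#' A nondecreasing time grid with nonincreasing survival probabilities and
#' S(0) = 1, evaluated as a right-continuous step function.
#'
#' @slot time numeric, nondecreasing times (months), starting at 0.
#' @slot surv numeric, survival probabilities in [0, 1], nonincreasing.
#'
#' @seealso [kmEstimate()], [predictSurvival()], [survivalAt()]
#' @export
setClass("SurvivalCurve",
  representation(time = "numeric", surv = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@surv))
      msg <- c(msg, "time and surv must have equal length")
    if (length(object@time) == 0L || object@time[1] != 0)
      msg <- c(msg, "curve must start at time 0")
    if (is.unsorted(object@time))
      msg <- c(msg, "time must be nondecreasing")
    if (any(diff(object@surv) > 1e-12))
      msg <- c(msg, "surv must be nonincreasing")
    if (abs(object@surv[1] - 1) > 1e-12)
      msg <- c(msg, "S(0) must be 1")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted neural Cox survival model
#'
#' A multilayer perceptron risk score trained with the Cox
#' partial-likelihood loss, together with the Breslow baseline cumulative
#' hazard estimated on the training set and the training-split
#' standardization statistics.
#'
#' @slot spec list, the network specification (see [networkSpec()]).
#' @slot weights list of layer weight matrices and bias vectors.
#' @slot baseline list with elements `time` and `hazard`: the Breslow
#'   cumulative baseline hazard step function (H0(0) = 0, nondecreasing).
#' @slot standardization list with `center` and `scale` per input column.
#' @slot log list of training metadata (epochs run, losses, timing).
#'
#' @seealso [trainSurvivalNetwork()], [predictRisk()], [predictSurvival()]
#' @export
setClass("SurvivalNetworkFit",
  representation(spec = "list", weights = "list", baseline = "list",
                 standardization = "list", log = "list"),
  validity = function(object) {
    msg <- character()
    b <- object@baseline
    if (length(b)) {
      if (any(diff(b$hazard) < -1e-12))
        msg <- c(msg, "baseline hazard must be nondecreasing")
    }
    if (length(msg)) msg else TRUE
  }
)
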