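#' Single-level stationary 3D Haar wavelet decomposition
#'
#' Applies a low-pass (L = averaging) or high-pass (H = differencing) Haar
#' filter along each of the three axes, producing the eight canonical
#' subbands LLL, LLH, ..., HHH used for wavelet radiomics. The transform
#' is undecimated (stationary), so every subband has the same shape and
#' spacing as the input, and uses periodic boundary handling, which makes
#' it exactly energy-preserving and perfectly invertible: the filter pair
#' is (1/2, 1/2) and (1/2, -1/2), for which the summed squared
#' coefficients over the eight subbands equal the squared input exactly.
#'
#' Subband labels follow the axis order (x, y, z): the first letter is the
#' filter applied along x, the second along y, the third along z.
#'
#' @param volume an [ImageVolume-class]; every axis must have length >= 2.
#' @return a [WaveletSet-class] with the original volume and 8 subbands.
#' @examples
#' ws <- waveletDecompose(imageVolume(array(rnorm(8^3), c(8, 8, 8))))
#' names(ws@subbands)
#' @export
waveletDecompose <- function(volume) {
  stopifnot(is(volume, "ImageVolume"))
  d <- dim(volume@values)
  if (any(d < 2)) stop("degenerate axis: every axis must have length >= 2")
  v <- volume@values
  pass <- function(arr, axis, filt) {
    nxt <- .shift_axis(arr, axis, 1L)
    if (filt == "L") (arr + nxt) / 2 else (arr - nxt) / 2
  }
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  subbands <- vector("list", 8L)
  names(subbands) <- labels
  for (lab in labels) {
    f <- strsplit(lab, "")[[1]]
    a <- pass(v, 1L, f[1])
    a <- pass(a, 2L, f[2])
    a <- pass(a, 3L, f[3])
    subbands[[lab]] <- imageVolume(a, spacing = volume@spacing,
                                   origin = volume@origin)
  }
  new("WaveletSet", original = volume, subbands = subbands)
}

#' Reconstruct a volume from its stationary wavelet subbands
#'
#' Exact inverse of [waveletDecompose()]; mainly used to verify the
#' transform.
#'
#' @param ws a [WaveletSet-class].
#' @return an [ImageVolume-class] equal to the original input.
#' @export
waveletReconstruct <- function(ws) {
  stopifnot(is(ws, "WaveletSet"))
  inv_pass <- function(L, H, axis) {
    # x[i] = L[i] + H[i]; also x[i] = L[i-1] - H[i-1]; average (both exact)
    a <- L + H
    b <- .shift_axis(L - H, axis, -1L)
    (a + b) / 2
  }
  sb <- ws@subbands
  # undo z first (third letter), then y, then x
  merge_axis <- function(pairs, axis) {
    out <- list()
    for (nm in names(pairs)) out[[nm]] <- pairs[[nm]]
    out
  }
  # collapse along z: combine *L and *H
  lvl2 <- list()
  for (p in c("LL", "LH", "HL", "HH"))
    lvl2[[p]] <- inv_pass(sb[[paste0(p, "L")]]@values,
                          sb[[paste0(p, "H")]]@values, 3L)
  lvl1 <- list()
  for (p in c("L", "H"))
    lvl1[[p]] <- inv_pass(lvl2[[paste0(p, "L")]], lvl2[[paste0(p, "H")]], 2L)
  v <- inv_pass(lvl1[["L"]], lvl1[["H"]], 1L)
  imageVolume(v, spacing = ws@original@spacing, origin = ws@original@origin)
}

# circular shift of a 3D array by k along the given axis (k = 1 brings
# element i+1 to position i)
.shift_axis <- function(arr, axis, k) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  n <- d[axis]
  idx[[axis]] <- ((seq_len(n) - 1 + k) %% n) + 1L
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}
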