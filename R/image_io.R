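#' Read and write 3D volumes as NIfTI
#'
#' `readVolume()` loads a 3D NIfTI file into an [ImageVolume-class];
#' `readMask()` loads one as a [RoiMask-class] (any nonzero voxel is
#' foreground). `writeVolume()` and `writeMask()` write them back with
#' spacing and origin in the header. Round-tripping preserves spacing
#' exactly and values to float precision.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `readVolume()`: an `ImageVolume`; `readMask()`: a `RoiMask`.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(imageVolume(array(rnorm(60), c(3, 4, 5))), f)
#' v <- readVolume(f)
#' dim(imgValues(v))
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4] == 1L) {
    im2 <- array(as.numeric(im), d[1:3])
    d <- d[1:3]
  } else if (length(d) == 3L) {
    im2 <- array(as.numeric(im), d)
  } else {
    stop("not a 3D volume: dimensions are (", paste(d, collapse = ", "), ")")
  }
  sp <- RNifti::pixdim(im)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in NIfTI header")
  xf <- RNifti::xform(im)
  orig <- as.numeric(xf[1:3, 4])
  imageVolume(im2, spacing = sp, origin = orig)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  roiMask(v@values != 0, spacing = v@spacing, origin = v@origin)
}

#' @rdname readVolume
#' @param volume an [ImageVolume-class] to write.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  .write_nifti(volume@values, volume@spacing, volume@origin, path)
  invisible(path)
}

#' @rdname readVolume
#' @param mask a [RoiMask-class] to write (stored as 0/1).
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "RoiMask"))
  .write_nifti(array(as.numeric(mask@values), dim(mask@values)),
               mask@spacing, mask@origin, path)
  invisible(path)
}

.write_nifti <- function(values, spacing, origin, path) {
  im <- RNifti::asNifti(values, list(
    pixdim = c(1, spacing, 0, 0, 0, 0),
    qoffset_x = origin[1], qoffset_y = origin[2], qoffset_z = origin[3],
    qform_code = 1L))
  RNifti::writeNifti(im, path)
}
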