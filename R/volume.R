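#' Masked 4D BOLD volume series
#'
#' Thin container pairing a 4D data array (x, y, z, t) with its repetition
#' time, a 3D brain mask and a voxel-to-world affine.
#'
#' @param data 4D numeric array.
#' @param tr Repetition time in seconds.
#' @param mask 3D logical array matching the spatial dims (default: all
#'   voxels in-brain).
#' @param affine 4x4 voxel-to-world transform (default: identity spacing).
#' @return A `volume_series` object.
#' @export
volume_series <- function(data, tr, mask = NULL, affine = NULL) {
  stopifnot(length(dim(data)) == 4L, tr > 0)
  sdim <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sdim)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), sdim))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match spatial dims ", paste(sdim, collapse = "x"))
  if (is.null(affine)) affine <- diag(4)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  structure(list(data = data, tr = tr, mask = mask, affine = affine),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat("volume_series:", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "volumes, TR =", x$tr, "s,", sum(x$mask), "in mask\n")
  invisible(x)
}

#' Number of volumes in a series
#' @param vol A `volume_series`.
#' @export
n_volumes <- function(vol) dim(vol$data)[4]

# time x in-mask-voxel matrix view of the 4D data
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m[as.vector(vol$mask), , drop = FALSE])
}

# embed an in-mask vector back into a 3D array (NA outside mask)
embed_in_mask <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}

#' Read a 4D NIfTI file as a volume series
#'
#' The repetition time is taken from the time-axis pixel dimension; the
#' affine from the stored xform.
#'
#' @param path NIfTI file (the 4D data).
#' @param mask_path Optional NIfTI path of a 3D mask (non-zero = in-brain).
#' @return A `volume_series`.
#' @export
read_nifti <- function(path, mask_path = NULL) {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  a <- array(as.vector(a), dim(a))   # drop RNifti's image attributes
  if (length(dim(a)) != 4L)
    stop("expected a 4D volume, got ", length(dim(a)), "D: ", path)
  tr <- RNifti::pixdim(im)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(m), dim(a)[1:3]))
      stop("mask spatial dims do not match the 4D volume")
    mask <- m != 0
  }
  volume_series(a, tr = tr, mask = mask, affine = unclass(RNifti::xform(im)))
}

#' Write a volume series (and optionally its mask) to NIfTI
#'
#' @param vol A `volume_series`.
#' @param path Output path for the 4D data.
#' @param mask_path Optional output path for the mask (uint8).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, mask_path = NULL) {
  stopifnot(inherits(vol, "volume_series"))
  im <- RNifti::asNifti(vol$data)
  RNifti::pixdim(im) <- c(abs(diag(vol$affine)[1:3]), vol$tr)
  RNifti::qform(im) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(im, path)
  if (!is.null(mask_path)) write_mask_nifti(vol$mask, vol$affine, mask_path)
  invisible(path)
}

#' Write a 3D mask or statistic map to NIfTI
#' @param map 3D array (logical masks are written as uint8).
#' @param affine 4x4 affine.
#' @param path Output path.
#' @export
write_mask_nifti <- function(map, affine, path) {
  lg <- is.logical(map)
  arr <- array(if (lg) as.integer(map) else as.numeric(map), dim(map))
  if (!lg) arr[is.na(arr)] <- 0
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- abs(diag(affine)[1:3])
  RNifti::qform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path, datatype = if (lg) "uint8" else "float")
  invisible(path)
}
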