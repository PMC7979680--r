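# NIfTI-1 I/O.  Scalar volumes are plain 3-D NIfTI; displacement fields are
# 4-D NIfTI with 3 components in the last dimension (world-axis mm) plus a
# JSON sidecar recording the convention tag; tensor volumes are 4-D with 6
# components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).

.niftiSidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

.writeNiftiArray <- function(arr, affine, path) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- voxelSpacing(affine)
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read / write scalar volumes as NIfTI
#'
#' @param path file path (.nii or .nii.gz).
#' @param isMask declare binary content on read.
#' @return an [ImageVolume-class].
#' @export
readNiftiVolume <- function(path, isMask = FALSE) {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim(im))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dim(arr)), " dimensions")
  A <- structure(RNifti::xform(im), imagedim = NULL, code = NULL)
  imageVolume(arr, affine = matrix(as.numeric(A), 4L, 4L), isMask = isMask)
}

#' @rdname readNiftiVolume
#' @param img an [ImageVolume-class].
#' @export
writeNiftiVolume <- function(img, path) {
  .writeNiftiArray(imgData(img), imgAffine(img), path)
}

#' Read / write displacement fields as 4-D NIfTI + JSON sidecar
#'
#' The sidecar (same basename, \code{.json}) records the convention tag,
#' units, and component frame.  On read, a missing sidecar falls back to the
#' \code{convention} argument.
#'
#' @param path file path (.nii or .nii.gz).
#' @param convention fallback convention when no sidecar is present.
#' @return a [VectorField-class].
#' @export
readVectorFieldNifti <- function(path, convention = "resampling") {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim(im))
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) {  # tolerate the x,y,z,1,3 vector layout
    arr <- array(arr, d[c(1:3, 5L)]); d <- dim(arr)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4-D NIfTI with 3 components in the last dimension")
  side <- .niftiSidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$convention)) convention <- meta$convention
  }
  A <- matrix(as.numeric(RNifti::xform(im)), 4L, 4L)
  vectorField(arr, affine = A, convention = convention)
}

#' @rdname readVectorFieldNifti
#' @param u a [VectorField-class].
#' @export
writeVectorFieldNifti <- function(u, path) {
  .writeNiftiArray(imgData(u), imgAffine(u), path)
  jsonlite::write_json(
    list(convention = fieldConvention(u), units = "mm",
         components = "world axes"),
    .niftiSidecarPath(path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write diffusion-tensor volumes as 4-D NIfTI
#'
#' Component order is Dxx, Dxy, Dxz, Dyy, Dyz, Dzz along the last dimension.
#'
#' @param path file path.
#' @return a [TensorVolume-class].
#' @export
readTensorVolumeNifti <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim(im))
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(arr, d[c(1:3, 5L)]); d <- dim(arr)
  }
  if (length(d) != 4L || d[4] != 6L)
    stop("expected a 4-D NIfTI with 6 tensor components")
  A <- matrix(as.numeric(RNifti::xform(im)), 4L, 4L)
  new("TensorVolume", data = arr, affine = A)
}

#' @rdname readTensorVolumeNifti
#' @param tv a [TensorVolume-class].
#' @export
writeTensorVolumeNifti <- function(tv, path) {
  .writeNiftiArray(imgData(tv), imgAffine(tv), path)
}
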