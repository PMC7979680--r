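# Generics and accessors.  Slot access goes through these everywhere.

#' @rdname ImageVolume-class
#' @param x an object.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname ImageVolume-class
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))
#' @rdname ImageVolume-class
#' @export
setGeneric("isMask", function(x) standardGeneric("isMask"))
#' @rdname VectorField-class
#' @param x an object.
#' @export
setGeneric("fieldConvention", function(x) standardGeneric("fieldConvention"))
#' @rdname HexMesh-class
#' @param x an object.
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))
#' @rdname HexMesh-class
#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))
#' @rdname HexMesh-class
#' @export
setGeneric("partId", function(x) standardGeneric("partId"))

setMethod("imgData", "ImageVolume", function(x) x@data)
setMethod("imgData", "VectorField", function(x) x@data)
setMethod("imgData", "TensorVolume", function(x) x@data)
setMethod("imgAffine", "ImageVolume", function(x) x@affine)
setMethod("imgAffine", "VectorField", function(x) x@affine)
setMethod("imgAffine", "TensorVolume", function(x) x@affine)
setMethod("isMask", "ImageVolume", function(x) x@isMask)
setMethod("fieldConvention", "VectorField", function(x) x@convention)
setMethod("meshNodes", "HexMesh", function(x) x@nodes)
setMethod("meshElements", "HexMesh", function(x) x@elements)
setMethod("partId", "HexMesh", function(x) x@partId)

#' @rdname QualityReport-class
#' @param x an object.
#' @export
setGeneric("qualityPass", function(x) standardGeneric("qualityPass"))
setMethod("qualityPass", "QualityReport", function(x) x@pass)

#' @rdname ElementFiberMap-class
#' @param x an object.
#' @export
setGeneric("fiberFa", function(x) standardGeneric("fiberFa"))
#' @rdname ElementFiberMap-class
#' @export
setGeneric("fiberV1", function(x) standardGeneric("fiberV1"))
setMethod("fiberFa", "ElementFiberMap", function(x) x@fa)
setMethod("fiberV1", "ElementFiberMap", function(x) x@v1)

#' @rdname CoraComponents-class
#' @param x an object.
#' @export
setGeneric("coraV", function(x) standardGeneric("coraV"))
#' @rdname CoraComponents-class
#' @export
setGeneric("coraG", function(x) standardGeneric("coraG"))
#' @rdname CoraComponents-class
#' @export
setGeneric("coraP", function(x) standardGeneric("coraP"))
setMethod("coraV", "CoraComponents", function(x) x@V)
setMethod("coraG", "CoraComponents", function(x) x@G)
setMethod("coraP", "CoraComponents", function(x) x@P)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  sp <- voxelSpacing(object@affine)
  cat(sprintf("ImageVolume %dx%dx%d, spacing %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3],
              if (object@isMask) " [mask]" else ""))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "VectorField", function(object) {
  d <- dim(object@data)
  mags <- sqrt(rowSums(matrix(object@data, ncol = 3L)^2))
  cat(sprintf("VectorField %dx%dx%d (%s), |u| max %.3g mm, mean %.3g mm\n",
              d[1], d[2], d[3], object@convention, max(mags), mean(mags)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngleDeg(object@rotation)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d nodes, %d hexahedral elements, %d part(s)\n",
              nrow(object@nodes), nrow(object@elements),
              length(unique(object@partId))))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport: min SJ %.4f | >=0.50: %.1f%% | >=0.45: %.1f%% | %s (floor %.2f)\n",
    object@minJacobian, 100 * object@fracGe050, 100 * object@fracGe045,
    if (object@pass) "PASS" else "FAIL", object@floor))
})

setMethod("show", "TensorVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("TensorVolume %dx%dx%d (6 components)\n", d[1], d[2], d[3]))
})

setMethod("show", "ElementFiberMap", function(object) {
  cat(sprintf("ElementFiberMap: %d elements, FA range [%.3f, %.3f], %d outside\n",
              length(object@fa),
              if (length(object@fa)) min(object@fa) else NA,
              if (length(object@fa)) max(object@fa) else NA,
              object@outsideCount))
})

setMethod("show", "FiberSet", function(object) {
  np <- vapply(object@lines, nrow, integer(1))
  cat(sprintf("FiberSet: %d tract(s), %d points total, step %.3g mm\n",
              length(object@lines), sum(np), object@step))
})

setMethod("show", "StrainHistory", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("StrainHistory: %d elements, %d frames over [%g, %g] ms\n",
              d[1], d[3], min(object@times), max(object@times)))
})

setMethod("show", "NodalHistory", function(object) {
  d <- dim(object@displacements)
  cat(sprintf("NodalHistory: %d nodes, %d frames over [%g, %g] ms\n",
              d[1], d[3], min(object@times), max(object@times)))
})

setMethod("show", "CoraComponents", function(object) {
  cat(sprintf("CoraComponents: V %.3f, G %.3f, P %.3f -> score %.3f (shift %.3g ms)\n",
              object@V, object@G, object@P,
              (object@V + object@G + object@P) / 3, object@bestShift))
})

setMethod("show", "PersonalizationResult", function(object) {
  cat("PersonalizationResult\n")
  show(object@rigid)
  show(object@fieldTotal)
  show(object@quality)
  if (length(object@diceTable)) {
    cat("  DICE: ")
    cat(paste(sprintf("%s %.3f", names(object@diceTable), object@diceTable),
              collapse = ", "), "\n")
  }
})
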