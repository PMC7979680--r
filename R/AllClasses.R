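#' @import methods
NULL

#' Scalar image volume on a regular voxel grid
#'
#' A 3-D scalar volume (e.g. a T1-weighted image, a binary cranial or brain
#' mask, or an integer region-label volume) together with its 4x4 voxel-to-world
#' affine.  World units are millimetres; voxel indices are 0-based with voxel
#' centres at integer indices, following the NIfTI convention.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices (homogeneous)
#'   to world coordinates in mm.  Must be invertible.
#' @slot isMask logical; \code{TRUE} declares binary content, in which case the
#'   data may contain only 0 and 1.
#'
#' @seealso [imageVolume()], [VectorField-class]
#' @export
setClass("ImageVolume",
  representation(data = "array", affine = "matrix", isMask = "logical"),
  prototype(isMask = FALSE))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (isTRUE(object@isMask) && length(object@data) &&
      !all(object@data %in% c(0, 1)))
    msg <- c(msg, "mask volumes may contain only {0,1}")
  if (length(msg)) msg else TRUE
})

#' Dense displacement field on a voxel grid
#'
#' A 3-component vector field (displacements in mm, expressed along world axes)
#' stored on a regular voxel grid.  Two conventions are first-class and always
#' tagged on the object:
#' \describe{
#'   \item{\code{"resampling"}}{pull-back semantics, used to warp images:
#'     \code{out(x) = in(x + u(x))}.}
#'   \item{\code{"forward"}}{push-forward semantics, used to move mesh nodes:
#'     \code{x' = x + u(x)}.}
#' }
#' [invertField()] converts between the two.
#'
#' @slot data 4-D numeric array, dimensions \code{c(nx, ny, nz, 3)}.
#' @slot affine 4x4 voxel-to-world matrix (see [ImageVolume-class]).
#' @slot convention either \code{"resampling"} or \code{"forward"}.
#'
#' @export
setClass("VectorField",
  representation(data = "array", affine = "matrix", convention = "character"))

setValidity("VectorField", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "data must be a 4-D array with 3 components in the last dimension")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all displacement components must be finite")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine[1:3, 1:3])) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(object@convention) != 1L ||
      !object@convention %in% c("resampling", "forward"))
    msg <- c(msg, "convention must be 'resampling' or 'forward'")
  if (length(msg)) msg else TRUE
})

#' Rigid (6 degree-of-freedom) transform
#'
#' A proper rotation plus translation, mapping moving-image world coordinates
#' onto fixed-image world coordinates: \code{x_fixed = R x_moving + t}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L)))
    msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det = +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' Hexahedral mesh
#'
#' Nodes in world mm and 8-node element connectivity in VTK hexahedron corner
#' ordering (nodes 0-3 the bottom face counter-clockwise, 4-7 the matching top
#' face), plus an integer part label per element.  Morphing updates nodal
#' coordinates only; connectivity and part labels are preserved.
#'
#' @slot nodes N x 3 numeric matrix, world mm.
#' @slot elements M x 8 integer matrix of 1-based node indices.
#' @slot partId integer vector, one label per element.
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elements = "matrix", partId = "integer"))

setValidity("HexMesh", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be N x 3")
  if (ncol(object@elements) != 8L) msg <- c(msg, "elements must be M x 8")
  if (nrow(object@elements)) {
    if (min(object@elements) < 1L || max(object@elements) > nrow(object@nodes))
      msg <- c(msg, "element node indices out of range")
    if (any(apply(object@elements, 1L, anyDuplicated) > 0L))
      msg <- c(msg, "degenerate element: repeated node within an element")
  }
  if (length(object@partId) != nrow(object@elements))
    msg <- c(msg, "partId must have one entry per element")
  if (length(msg)) msg else TRUE
})

#' Element quality report (scaled Jacobian)
#'
#' Summary of per-element corner-based scaled Jacobians with the acceptance
#' gate used for morphed meshes: pass requires at least 95\% of elements with
#' scaled Jacobian >= 0.5 and a minimum not below \code{floor}.
#'
#' @slot minJacobian smallest scaled Jacobian over all elements.
#' @slot fracGe050 fraction of elements with scaled Jacobian >= 0.5.
#' @slot fracGe045 fraction of elements with scaled Jacobian >= 0.45.
#' @slot pass logical gate outcome.
#' @slot floor minimum-Jacobian gate threshold used.
#' @slot perElement numeric vector of per-element values (may be length 0 when
#'   not retained).
#' @export
setClass("QualityReport",
  representation(minJacobian = "numeric", fracGe050 = "numeric",
                 fracGe045 = "numeric", pass = "logical", floor = "numeric",
                 perElement = "numeric"))

setValidity("QualityReport", function(object) {
  msg <- character()
  if (object@fracGe050 < 0 || object@fracGe050 > 1 ||
      object@fracGe045 < 0 || object@fracGe045 > 1)
    msg <- c(msg, "fractions must lie in [0,1]")
  expect <- object@fracGe050 >= 0.95 && object@minJacobian >= object@floor
  if (!identical(object@pass, expect))
    msg <- c(msg, "pass flag inconsistent with gate definition")
  if (length(msg)) msg else TRUE
})

#' Diffusion-tensor volume
#'
#' Per-voxel symmetric 3x3 diffusion tensors, stored as 6 components in the
#' order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#'
#' @slot data 4-D numeric array \code{c(nx, ny, nz, 6)}.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("TensorVolume",
  representation(data = "array", affine = "matrix"))

setValidity("TensorVolume", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 4L || d[4] != 6L)
    msg <- c(msg, "data must be a 4-D array with 6 tensor components")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine[1:3, 1:3])) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Per-element fiber map
#'
#' For each element of a mesh: the fractional anisotropy and the unit first
#' eigenvector of the diffusion tensor at the voxel nearest the element
#' centroid.  This is the per-element fiber direction used for axonal-strain
#' projection.
#'
#' @slot fa numeric vector in [0,1], one value per element.
#' @slot v1 M x 3 matrix of unit vectors.
#' @slot outsideCount number of element centroids falling outside the tensor
#'   volume (assigned FA 0 and the x axis).
#' @export
setClass("ElementFiberMap",
  representation(fa = "numeric", v1 = "matrix", outsideCount = "integer"))

setValidity("ElementFiberMap", function(object) {
  msg <- character()
  if (nrow(object@v1) != length(object@fa))
    msg <- c(msg, "fa and v1 must have matching element counts")
  if (length(object@fa)) {
    if (any(object@fa < -1e-12 | object@fa > 1 + 1e-12))
      msg <- c(msg, "FA values must lie in [0,1]")
    nrm <- sqrt(rowSums(object@v1^2))
    if (max(abs(nrm - 1)) > 1e-9)
      msg <- c(msg, "fiber directions must be unit vectors (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Set of streamline fiber tracts
#'
#' Polylines (sequences of world-mm points) produced by streamline tracking,
#' each with its seed id and mean-FA attribute.
#'
#' @slot lines list of k x 3 numeric matrices.
#' @slot seedId integer vector, one per line.
#' @slot meanFa numeric vector, one per line.
#' @slot step step length (mm) used during integration.
#' @export
setClass("FiberSet",
  representation(lines = "list", seedId = "integer", meanFa = "numeric",
                 step = "numeric"))

setValidity("FiberSet", function(object) {
  msg <- character()
  n <- length(object@lines)
  if (length(object@seedId) != n || length(object@meanFa) != n)
    msg <- c(msg, "seedId and meanFa must have one entry per line")
  for (ln in object@lines) {
    if (!is.matrix(ln) || ncol(ln) != 3L) {
      msg <- c(msg, "each line must be a k x 3 matrix"); break
    }
    if (nrow(ln) > 1L) {
      sp <- sqrt(rowSums(diff(ln)^2))
      if (any(sp > object@step + 1e-9)) {
        msg <- c(msg, "consecutive point spacing exceeds the step size"); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Nodal displacement history
#'
#' Time histories of nodal displacements (mm) for every node of a mesh.  The
#' first frame is the reference configuration and must be identically zero.
#'
#' @slot times strictly increasing times, ms.
#' @slot displacements array \code{c(nNodes, 3, nTimes)}, mm.
#' @export
setClass("NodalHistory",
  representation(times = "numeric", displacements = "array"))

setValidity("NodalHistory", function(object) {
  msg <- character()
  d <- dim(object@displacements)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "displacements must be nNodes x 3 x nTimes")
  else if (d[3] != length(object@times))
    msg <- c(msg, "time axis length mismatch")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@times) && max(abs(object@displacements[, , 1L])) > 1e-12)
    msg <- c(msg, "first frame must be the zero reference configuration")
  if (length(msg)) msg else TRUE
})

#' Element strain history
#'
#' Per-element symmetric Green-Lagrange strain tensors over time.  Components
#' are stored in the order Exx, Eyy, Ezz, Exy, Eyz, Ezx using tensor shear
#' (Exy = gamma/2), not engineering shear.
#'
#' @slot times strictly increasing times, ms.
#' @slot tensors array \code{c(nElements, 6, nTimes)}.
#' @export
setClass("StrainHistory",
  representation(times = "numeric", tensors = "array"))

setValidity("StrainHistory", function(object) {
  msg <- character()
  d <- dim(object@tensors)
  if (length(d) != 3L || d[2] != 6L)
    msg <- c(msg, "tensors must be nElements x 6 x nTimes")
  else if (d[3] != length(object@times))
    msg <- c(msg, "time axis length mismatch")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@times) && max(abs(object@tensors[, , 1L])) > 1e-12)
    msg <- c(msg, "frame 0 tensors must be identically zero")
  if (length(msg)) msg else TRUE
})

#' Demons registration settings
#'
#' Multi-resolution schedule and regularization parameters for diffeomorphic
#' demons registration.  All length scales are in voxels of the registration
#' grid.
#'
#' @slot pyramidFactors integer downsampling factors, coarse to fine.
#' @slot itersPerLevel iteration counts, one per pyramid level.
#' @slot sigmaUpdate Gaussian sigma (voxels) smoothing each force update.
#' @slot sigmaField Gaussian sigma (voxels) smoothing the accumulated velocity.
#' @slot maxStep cap on the per-iteration force magnitude, voxels.
#' @slot squaringMin minimum number of scaling-and-squaring steps used when
#'   exponentiating the velocity field.
#' @export
setClass("DemonsSettings",
  representation(pyramidFactors = "integer", itersPerLevel = "integer",
                 sigmaUpdate = "numeric", sigmaField = "numeric",
                 maxStep = "numeric", squaringMin = "integer"))

setValidity("DemonsSettings", function(object) {
  msg <- character()
  if (length(object@pyramidFactors) != length(object@itersPerLevel))
    msg <- c(msg, "pyramidFactors and itersPerLevel must have equal length")
  if (object@sigmaUpdate <= 0 || object@sigmaField <= 0)
    msg <- c(msg, "sigmas must be > 0")
  if (object@maxStep <= 0) msg <- c(msg, "maxStep must be > 0")
  if (length(msg)) msg else TRUE
})

#' CORA cross-correlation settings
#'
#' Parameters of the cross-correlation sub-method: admissible time-shift
#' window as fractions of the evaluation-interval length, the exponents of the
#' shape/size/phase sub-ratings, an optional fixed evaluation interval, and an
#' optional resampling step.
#'
#' @slot dMin shift fraction below which phase is rated 1.
#' @slot dMax largest admissible shift fraction (phase rated 0 at or beyond).
#' @slot kV,kG,kP exponents of the V, G, P sub-ratings.
#' @slot interval optional \code{c(tMin, tMax)} ms; \code{NA} = overlap of the
#'   two curves.
#' @slot resampleDt optional uniform resampling step, ms; \code{NA} = the
#'   smaller of the two native median steps.
#' @export
setClass("CoraSettings",
  representation(dMin = "numeric", dMax = "numeric", kV = "numeric",
                 kG = "numeric", kP = "numeric", interval = "numeric",
                 resampleDt = "numeric"))

setValidity("CoraSettings", function(object) {
  msg <- character()
  if (!(object@dMin >= 0 && object@dMin < object@dMax && object@dMax <= 1))
    msg <- c(msg, "require 0 <= dMin < dMax <= 1")
  if (object@kV <= 0 || object@kG <= 0 || object@kP <= 0)
    msg <- c(msg, "exponents must be > 0")
  if (length(msg)) msg else TRUE
})

#' CORA sub-ratings for one curve pair
#'
#' Shape (V), size (G) and phase (P) sub-ratings in [0,1], the best time shift
#' found by cross-correlation, and the evaluation interval used.  The combined
#' score is their equal-weight mean, see [coraScore()].
#'
#' @slot V,G,P sub-ratings in [0,1].
#' @slot bestShift time shift maximizing the cross-correlation, ms.
#' @slot interval evaluation interval \code{c(tMin, tMax)}, ms.
#' @export
setClass("CoraComponents",
  representation(V = "numeric", G = "numeric", P = "numeric",
                 bestShift = "numeric", interval = "numeric"))

setValidity("CoraComponents", function(object) {
  v <- c(object@V, object@G, object@P)
  if (any(v < -1e-12 | v > 1 + 1e-12))
    "V, G, P must lie in [0,1]" else TRUE
})

#' Result of the hierarchical personalization pipeline
#'
#' Bundles every product of [personalize()]: the rigid pre-alignment, the two
#' stage displacement fields and their composition, the warped baseline T1,
#' the morphed mesh with its quality report, and the DICE table against the
#' subject's labels when provided.
#'
#' @slot rigid the subject-to-baseline [RigidTransform-class].
#' @slot field1 stage-1 (cranial-mask demons) resampling field.
#' @slot field2 stage-2 (intensity demons or imported) resampling field.
#' @slot fieldTotal composed resampling field.
#' @slot warpedT1 baseline T1 resampled through \code{fieldTotal}.
#' @slot morphedMesh baseline mesh moved by the inverse (forward) field.
#' @slot quality [QualityReport-class] of the morphed mesh.
#' @slot diceTable named numeric vector of per-region DICE values (may be
#'   empty when no label volumes were supplied).
#' @slot ssdTrace list of per-level SSD traces from the two demons stages.
#' @export
setClass("PersonalizationResult",
  representation(rigid = "RigidTransform", field1 = "VectorField",
                 field2 = "VectorField", fieldTotal = "VectorField",
                 warpedT1 = "ImageVolume", morphedMesh = "HexMesh",
                 quality = "QualityReport", diceTable = "numeric",
                 ssdTrace = "list"))

setValidity("PersonalizationResult", function(object) {
  if (length(object@diceTable) &&
      any(object@diceTable < -1e-12 | object@diceTable > 1 + 1e-12))
    "DICE values must lie in [0,1]" else TRUE
})
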