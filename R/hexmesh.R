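# Hexahedral mesh model: construction, corner-based scaled-Jacobian quality,
# morphing by a forward displacement field, and image-driven region labeling.

#' Construct a HexMesh
#'
#' @param nodes N x 3 numeric matrix of node coordinates, world mm.
#' @param elements M x 8 matrix of 1-based node indices in VTK hexahedron
#'   corner ordering (0-3 bottom face counter-clockwise, 4-7 the top face).
#' @param partId integer part label per element (default all 1).
#' @return a [HexMesh-class].
#' @export
hexMesh <- function(nodes, elements, partId = rep(1L, nrow(elements))) {
  storage.mode(elements) <- "integer"
  new("HexMesh", nodes = nodes, elements = elements,
      partId = as.integer(partId))
}

# At each corner, the three emanating edges ordered so that a reference cube
# gives det = +1 (right-handed triads under VTK corner ordering).
.hexCornerTriads <- matrix(c(
  1L, 3L, 4L,   # corner 0 -> 1, 3, 4
  2L, 0L, 5L,
  3L, 1L, 6L,
  0L, 2L, 7L,
  7L, 5L, 0L,
  4L, 6L, 1L,
  5L, 7L, 2L,
  6L, 4L, 3L), ncol = 3L, byrow = TRUE) + 1L

#' Corner-based scaled Jacobian of hexahedral elements
#'
#' For each corner, the three emanating edge vectors e1, e2, e3 give
#' \code{J_c = det[e1 e2 e3] / (|e1| |e2| |e3|)}; the element value is the
#' minimum over the 8 corners.  The metric lies in [-1, 1], equals 1 for any
#' axis-orthogonal box, is invariant to rigid motion and uniform scaling, and
#' is negative exactly when a corner is inverted.
#'
#' @param corners for the single-element form, an 8 x 3 matrix of corner
#'   coordinates in VTK order.
#' @return scalar in [-1, 1].
#' @export
scaledJacobian <- function(corners) {
  .scaledJacobianMat(array(corners, c(1L, 8L, 3L)))[1L]
}

# Vectorized over elements: X is nElem x 8 x 3.
.scaledJacobianMat <- function(X) {
  m <- dim(X)[1]
  sj <- rep(Inf, m)
  for (c0 in 1:8) {
    tri <- .hexCornerTriads[c0, ]
    e1 <- X[, tri[1], , drop = FALSE] - X[, c0, , drop = FALSE]
    e2 <- X[, tri[2], , drop = FALSE] - X[, c0, , drop = FALSE]
    e3 <- X[, tri[3], , drop = FALSE] - X[, c0, , drop = FALSE]
    dim(e1) <- dim(e2) <- dim(e3) <- c(m, 3L)
    det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
            e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
            e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    nn <- sqrt(rowSums(e1^2) * rowSums(e2^2) * rowSums(e3^2))
    if (any(nn < 1e-30))
      stop("zero-length edge in element ", which(nn < 1e-30)[1])
    sj <- pmin(sj, det3 / nn)
  }
  sj
}

.elementCornerArray <- function(mesh) {
  el <- meshElements(mesh)
  m <- nrow(el)
  X <- array(0, c(m, 8L, 3L))
  nodes <- meshNodes(mesh)
  for (c0 in 1:8) X[, c0, ] <- nodes[el[, c0], , drop = FALSE]
  X
}

#' Element centroids
#' @param mesh a [HexMesh-class].
#' @return M x 3 matrix of centroid coordinates, mm.
#' @export
elementCentroids <- function(mesh) {
  el <- meshElements(mesh)
  nodes <- meshNodes(mesh)
  ctr <- matrix(0, nrow(el), 3L)
  for (c0 in 1:8) ctr <- ctr + nodes[el[, c0], , drop = FALSE]
  ctr / 8
}

#' Mesh quality report with the morphing acceptance gate
#'
#' Computes the per-element scaled Jacobian and the exact element-count
#' fractions at the 0.5 and 0.45 thresholds.  The gate passes when at least
#' 95\% of elements have scaled Jacobian >= 0.5 and the minimum is not below
#' \code{floor} (default 0.2); both gates are separate and both must hold.
#'
#' @param mesh a [HexMesh-class].
#' @param floor minimum-Jacobian threshold.
#' @param keepPerElement retain the per-element vector in the report.
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(mesh, floor = 0.2, keepPerElement = TRUE) {
  sj <- .scaledJacobianMat(.elementCornerArray(mesh))
  m <- length(sj)
  f50 <- sum(sj >= 0.5) / m
  f45 <- sum(sj >= 0.45) / m
  new("QualityReport", minJacobian = min(sj), fracGe050 = f50,
      fracGe045 = f45, pass = f50 >= 0.95 && min(sj) >= floor,
      floor = floor, perElement = if (keepPerElement) sj else numeric(0))
}

#' Morph a mesh by a forward displacement field
#'
#' Nodes move to \code{x' = x + u(x)}; element connectivity and part labels
#' are untouched.  Nodes outside the field domain raise an error listing the
#' offending node.
#'
#' @param mesh a [HexMesh-class].
#' @param forwardField a [VectorField-class] with convention
#'   \code{"forward"} (use [invertField()] on a registration output).
#' @return the morphed [HexMesh-class].
#' @export
morphMesh <- function(mesh, forwardField) {
  if (fieldConvention(forwardField) != "forward")
    stop("morphMesh requires a field in the 'forward' convention; got '",
         fieldConvention(forwardField),
         "' (invert a resampling field first)")
  u <- sampleTrilinear(forwardField, meshNodes(mesh), outside = "error")
  hexMesh(meshNodes(mesh) + u, meshElements(mesh), partId(mesh))
}

#' Region code enumeration for element labeling
#'
#' The fixed region vocabulary used throughout strain post-processing:
#' background 0, cerebral gray matter 1, cerebral white matter 2, corpus
#' callosum 3, brain stem 4, hippocampus 5, thalamus 6, cerebellum 7,
#' ventricles 8.
#'
#' @return named integer vector of region codes.
#' @export
regionCodes <- function() {
  c(background = 0L, cerebralGM = 1L, cerebralWM = 2L, CC = 3L, BS = 4L,
    hippocampus = 5L, thalamus = 6L, cerebellum = 7L, ventricles = 8L)
}

# Regions with coherent fiber orientation; axonal strain is evaluated only
# here (gray-matter structures such as thalamus/hippocampus are excluded).
anisotropicRegionCodes <- function() {
  regionCodes()[c("cerebralWM", "CC", "BS")]
}

#' Label mesh elements from a segmented image
#'
#' Each element takes the integer label of the voxel nearest its centroid
#' (ties go to the lowest linear index).  Centroids outside the label volume
#' map to background, with a warning stating the count.
#'
#' @param mesh a [HexMesh-class].
#' @param labels an integer-valued [ImageVolume-class].
#' @return a factor of length M with levels named after [regionCodes()]
#'   where the codes match, otherwise the bare integer codes.
#' @export
labelElementsByImage <- function(mesh, labels) {
  arr <- imgData(labels)
  if (max(abs(arr - round(arr))) > 1e-9)
    stop("label volume must be integer-valued")
  d <- dim(arr)
  ctr <- worldToVoxel(imgAffine(labels), elementCentroids(mesh))
  inside <- ctr[, 1] >= -0.5 & ctr[, 1] <= d[1] - 0.5 &
            ctr[, 2] >= -0.5 & ctr[, 2] <= d[2] - 0.5 &
            ctr[, 3] >= -0.5 & ctr[, 3] <= d[3] - 0.5
  lab <- integer(nrow(ctr))
  if (any(inside))
    lab[inside] <- arr[.sampleNearestIdx(ctr[inside, , drop = FALSE], d)]
  if (any(!inside))
    warning(sum(!inside), " element centroid(s) outside the label volume; ",
            "assigned background")
  codes <- regionCodes()
  lv <- sort(unique(c(codes, lab)))
  nm <- names(codes)[match(lv, codes)]
  nm[is.na(nm)] <- as.character(lv[is.na(nm)])
  factor(lab, levels = lv, labels = nm)
}
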