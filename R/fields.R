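# Scalar volumes and displacement fields: sampling, warping, composition,
# inversion.  This is the algebra that links image registration to mesh
# morphing.  All world units are mm; voxel indices are 0-based with voxel
# centres at integer indices (NIfTI convention).

#' Build a voxel-to-world affine from spacing and origin
#'
#' @param spacing voxel spacing, mm (length 3).
#' @param origin world coordinates of voxel (0,0,0), mm.
#' @return 4x4 affine matrix.
#' @export
affineFromSpacing <- function(spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(spacing, 3L)
  A[1:3, 4] <- origin
  A
}

#' Voxel spacing encoded in an affine
#' @param affine 4x4 voxel-to-world matrix.
#' @return length-3 spacing, mm.
#' @export
voxelSpacing <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

rotationAngleDeg <- function(R) {
  c2 <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c2))) * 180 / pi
}

#' Construct an ImageVolume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; alternatively give \code{spacing}
#'   and \code{origin}.
#' @param spacing,origin used when \code{affine} is missing.
#' @param isMask declare binary content.
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(data, affine = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), isMask = FALSE) {
  if (is.null(affine)) affine <- affineFromSpacing(spacing, origin)
  new("ImageVolume", data = data, affine = affine, isMask = isMask)
}

#' Construct a VectorField
#'
#' @param data 4-D array \code{c(nx, ny, nz, 3)}, displacements in mm along
#'   world axes.
#' @param affine 4x4 voxel-to-world matrix; alternatively \code{spacing} and
#'   \code{origin}.
#' @param convention \code{"resampling"} (pull-back, warps images) or
#'   \code{"forward"} (push-forward, moves mesh nodes).
#' @param spacing,origin used when \code{affine} is missing.
#' @return a [VectorField-class].
#' @export
vectorField <- function(data, affine = NULL, convention = "resampling",
                        spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(affine)) affine <- affineFromSpacing(spacing, origin)
  new("VectorField", data = data, affine = affine, convention = convention)
}

#' Construct a rigid transform
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric, mm.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation)
}

#' Invert a rigid transform
#' @param rigid a [RigidTransform-class].
#' @return the inverse transform.
#' @export
rigidInverse <- function(rigid) {
  Rt <- t(rigid@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% rigid@translation))
}

#' Compose two rigid transforms (apply \code{b} first, then \code{a})
#' @param a,b [RigidTransform-class] objects.
#' @return the composition a o b.
#' @export
rigidCompose <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation + a@translation))
}

#' Apply a rigid transform to points
#' @param rigid a [RigidTransform-class].
#' @param points N x 3 matrix of world coordinates, mm.
#' @return N x 3 matrix.
#' @export
applyRigid <- function(rigid, points) {
  points <- rbind3(points)
  sweep(points %*% t(rigid@rotation), 2L, -rigid@translation)
}

rbind3 <- function(points) {
  if (is.null(dim(points))) matrix(points, ncol = 3L) else points
}

worldToVoxel <- function(affine, points) {
  Ainv <- solve(affine[1:3, 1:3])
  sweep(rbind3(points), 2L, affine[1:3, 4]) %*% t(Ainv)
}

voxelToWorld <- function(affine, vox) {
  sweep(rbind3(vox) %*% t(affine[1:3, 1:3]), 2L, -affine[1:3, 4])
}

# World coordinates of every voxel centre, in array (column-major) order.
gridWorldCoords <- function(dims, affine) {
  i <- rep.int(0:(dims[1] - 1L), dims[2] * dims[3])
  j <- rep.int(rep(0:(dims[2] - 1L), each = dims[1]), dims[3])
  k <- rep(0:(dims[3] - 1L), each = dims[1] * dims[2])
  voxelToWorld(affine, cbind(i, j, k))
}

# Bounds check + clamp of voxel coordinates.  Beyond `tol` voxels outside the
# grid the default policy is a hard error naming the first offending point
# (silent zero-fill would corrupt mesh morphing); within it, coordinates are
# clamped.  outside = "clamp" clamps unconditionally.
.clampVox <- function(vox, dims, outside, tol = 0.5) {
  if (outside == "error") {
    for (a in 1:3) {
      bad <- which(vox[, a] < -tol | vox[, a] > dims[a] - 1 + tol)
      if (length(bad)) {
        b <- bad[1L]
        stop(sprintf(
          "point %d at voxel coordinate (%.3f, %.3f, %.3f) lies outside the grid [%d x %d x %d] by more than %.2f voxel",
          b, vox[b, 1], vox[b, 2], vox[b, 3], dims[1], dims[2], dims[3], tol))
      }
    }
  }
  for (a in 1:3) {
    vox[, a] <- pmin(pmax(vox[, a], 0), dims[a] - 1L)
  }
  vox
}

# Trilinear interpolation weights/corner indices shared across components.
.trilinearPrep <- function(vox, dims) {
  i0 <- pmin(floor(vox[, 1]), dims[1] - 2L); fx <- vox[, 1] - i0
  j0 <- pmin(floor(vox[, 2]), dims[2] - 2L); fy <- vox[, 2] - j0
  k0 <- pmin(floor(vox[, 3]), dims[3] - 2L); fz <- vox[, 3] - k0
  if (any(dims < 2L)) stop("trilinear sampling needs at least 2 voxels per axis")
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  base <- 1 + i0 + nx * j0 + nxy * k0
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  list(idx = list(base,            base + 1,
                  base + nx,       base + 1 + nx,
                  base + nxy,      base + 1 + nxy,
                  base + nx + nxy, base + 1 + nx + nxy),
       w = list(gx * gy * gz, fx * gy * gz, gx * fy * gz, fx * fy * gz,
                gx * gy * fz, fx * gy * fz, gx * fy * fz, fx * fy * fz))
}

# Sample a 3-D array (or one component block of a 4-D array via `offset`).
.sampleTrilinearVec <- function(arr, prep, offset = 0L) {
  out <- 0
  for (c in 1:8) out <- out + prep$w[[c]] * arr[prep$idx[[c]] + offset]
  out
}

.sampleNearestIdx <- function(vox, dims) {
  # Tie-break: a coordinate exactly half-way between two voxels goes to the
  # lower index on each axis, hence the lowest linear index overall.
  i <- pmin(pmax(ceiling(vox[, 1] - 0.5), 0), dims[1] - 1L)
  j <- pmin(pmax(ceiling(vox[, 2] - 0.5), 0), dims[2] - 1L)
  k <- pmin(pmax(ceiling(vox[, 3] - 0.5), 0), dims[3] - 1L)
  1 + i + dims[1] * j + dims[1] * dims[2] * k
}

#' Sample a volume or displacement field at world points
#'
#' Trilinear interpolation in voxel space.  Linear functions of position are
#' reproduced exactly.  Points farther than \code{tol} voxels outside the grid
#' raise an error naming the point (policy \code{outside = "error"}, the
#' default); within the tolerance, and always under \code{outside = "clamp"},
#' coordinates are clamped to the grid.
#'
#' @param field an [ImageVolume-class], [VectorField-class] or
#'   [TensorVolume-class].
#' @param points N x 3 matrix of world coordinates, mm.
#' @param outside \code{"error"} or \code{"clamp"}.
#' @param tol out-of-domain tolerance in voxels for the error policy.
#' @return numeric vector (scalar volume) or N x k matrix (vector/tensor
#'   volume).
#' @export
sampleTrilinear <- function(field, points, outside = c("error", "clamp"),
                            tol = 0.5) {
  outside <- match.arg(outside)
  points <- rbind3(points)
  if (!all(is.finite(points))) stop("points must be finite")
  d <- dim(imgData(field))
  vox <- .clampVox(worldToVoxel(imgAffine(field), points), d[1:3], outside, tol)
  prep <- .trilinearPrep(vox, d[1:3])
  arr <- imgData(field)
  if (length(d) == 3L) return(.sampleTrilinearVec(arr, prep))
  nvox <- prod(d[1:3])
  out <- matrix(0, nrow(points), d[4])
  for (c in seq_len(d[4]))
    out[, c] <- .sampleTrilinearVec(arr, prep, offset = (c - 1L) * nvox)
  out
}

#' Sample a volume at world points with nearest-voxel lookup
#'
#' Ties (coordinates exactly on a voxel boundary) go to the lowest linear
#' index, deterministically across platforms.
#'
#' @inheritParams sampleTrilinear
#' @return as [sampleTrilinear()].
#' @export
sampleNearest <- function(field, points, outside = c("error", "clamp"),
                          tol = 0.5) {
  outside <- match.arg(outside)
  points <- rbind3(points)
  d <- dim(imgData(field))
  vox <- .clampVox(worldToVoxel(imgAffine(field), points), d[1:3], outside, tol)
  lin <- .sampleNearestIdx(vox, d[1:3])
  arr <- imgData(field)
  if (length(d) == 3L) return(arr[lin])
  nvox <- prod(d[1:3])
  out <- matrix(0, nrow(points), d[4])
  for (c in seq_len(d[4])) out[, c] <- arr[lin + (c - 1L) * nvox]
  out
}

#' Warp an image through a resampling displacement field
#'
#' Computes \code{out(x) = img(x + u(x))} on the field's grid.  Nearest
#' interpolation preserves label sets and the mask flag; linear interpolation
#' drops the mask flag.  Out-of-domain lookups clamp at the image boundary
#' (image resampling near the boundary routinely maps slightly outside; point
#' sampling at mesh nodes keeps the strict error policy instead).
#'
#' @param img an [ImageVolume-class].
#' @param u a [VectorField-class] with convention \code{"resampling"}.
#' @param interp \code{"linear"} or \code{"nearest"}.
#' @return an [ImageVolume-class] on \code{u}'s grid.
#' @export
warpImage <- function(img, u, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (fieldConvention(u) != "resampling")
    stop("warpImage requires a field in the 'resampling' convention; got '",
         fieldConvention(u), "'")
  d <- dim(imgData(u))
  pts <- gridWorldCoords(d[1:3], imgAffine(u)) + matrix(imgData(u), ncol = 3L)
  vals <- if (interp == "linear") sampleTrilinear(img, pts, outside = "clamp")
          else sampleNearest(img, pts, outside = "clamp")
  imageVolume(array(vals, d[1:3]), affine = imgAffine(u),
              isMask = isMask(img) && interp == "nearest")
}

#' Compose two displacement fields
#'
#' True composition on \code{u1}'s grid:
#' \code{u_total(x) = u1(x) + u2(x + u1(x))}, so that
#' \code{(id + u_total) = (id + u2') o (id + u1)} in resampling order (the
#' image is first looked up through \code{u1}, then \code{u2}).  A literal
#' voxelwise \code{mode = "sum"} is also available (the two stage fields of
#' the hierarchical pipeline are described as "adding up"); it requires both
#' fields on the same grid.
#'
#' @param u1,u2 [VectorField-class] objects sharing one convention.
#' @param mode \code{"compose"} (default) or \code{"sum"}.
#' @param outside out-of-domain policy when sampling \code{u2}.
#' @return a [VectorField-class] on \code{u1}'s grid.
#' @export
composeFields <- function(u1, u2, mode = c("compose", "sum"),
                          outside = c("error", "clamp")) {
  mode <- match.arg(mode)
  outside <- match.arg(outside)
  if (fieldConvention(u1) != fieldConvention(u2))
    stop("cannot compose fields with different conventions ('",
         fieldConvention(u1), "' vs '", fieldConvention(u2), "')")
  d <- dim(imgData(u1))
  if (mode == "sum") {
    if (!identical(dim(imgData(u2)), d) ||
        max(abs(imgAffine(u1) - imgAffine(u2))) > 1e-8)
      stop("mode 'sum' requires both fields on the same grid")
    return(vectorField(imgData(u1) + imgData(u2), affine = imgAffine(u1),
                       convention = fieldConvention(u1)))
  }
  U1 <- matrix(imgData(u1), ncol = 3L)
  pts <- gridWorldCoords(d[1:3], imgAffine(u1)) + U1
  U2 <- sampleTrilinear(u2, pts, outside = outside)
  vectorField(array(U1 + U2, d), affine = imgAffine(u1),
              convention = fieldConvention(u1))
}

#' Determinant of the deformation gradient of id + u
#'
#' Central-difference Jacobian determinant of the map \code{x -> x + u(x)} in
#' voxel coordinates, evaluated at interior voxels.  Positive everywhere is
#' the numerical certificate that a field is diffeomorphic (non-folding).
#'
#' @param u a [VectorField-class].
#' @return 3-D array of determinants of size \code{dim - 2} (interior voxels).
#' @export
jacobianDeterminant <- function(u) {
  d <- dim(imgData(u))
  A3 <- imgAffine(u)[1:3, 1:3]
  Ainv <- solve(A3)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # displacement in voxel units
  U <- matrix(imgData(u), ncol = 3L) %*% t(Ainv)
  uv <- array(U, d)
  ii <- 2:(nx - 1); jj <- 2:(ny - 1); kk <- 2:(nz - 1)
  g <- function(comp, axis) {
    a <- uv[, , , comp]
    switch(axis,
      (a[3:nx, jj, kk] - a[1:(nx - 2), jj, kk]) / 2,
      (a[ii, 3:ny, kk] - a[ii, 1:(ny - 2), kk]) / 2,
      (a[ii, jj, 3:nz] - a[ii, jj, 1:(nz - 2)]) / 2)
  }
  F11 <- 1 + g(1, 1); F12 <- g(1, 2); F13 <- g(1, 3)
  F21 <- g(2, 1); F22 <- 1 + g(2, 2); F23 <- g(2, 3)
  F31 <- g(3, 1); F32 <- g(3, 2); F33 <- 1 + g(3, 3)
  F11 * (F22 * F33 - F23 * F32) -
    F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration \code{v_{k+1}(x) = -u(x + v_k(x))}.  The returned
#' field \code{v} satisfies \code{max_x |u(x + v(x)) + v(x)| <= tol}, i.e.
#' \code{(id + u) o (id + v) = id} within tolerance.  The convention tag is
#' flipped: the inverse of a resampling (pull-back) field is the forward
#' (push-forward) field used to move mesh nodes, and vice versa.
#'
#' @param u a [VectorField-class]; expected diffeomorphic.  A non-positive
#'   Jacobian determinant triggers a warning and best-effort inversion.
#' @param tol convergence tolerance in mm; default 0.01 voxel.
#' @param maxIter maximum fixed-point iterations.
#' @return a [VectorField-class] on the same grid, opposite convention.
#' @export
invertField <- function(u, tol = NULL, maxIter = 30L) {
  d <- dim(imgData(u))
  sp <- voxelSpacing(imgAffine(u))
  if (is.null(tol)) tol <- 0.01 * min(sp)
  diffeo <- TRUE
  if (min(jacobianDeterminant(u)) <= 0) {
    diffeo <- FALSE
    warning("field is not diffeomorphic (non-positive Jacobian determinant); ",
            "returning best-effort inverse")
  }
  P <- gridWorldCoords(d[1:3], imgAffine(u))
  V <- -matrix(imgData(u), ncol = 3L)
  res <- Inf
  for (it in seq_len(maxIter)) {
    Uv <- sampleTrilinear(u, P + V, outside = "clamp")
    res <- max(sqrt(rowSums((Uv + V)^2)))
    if (res <= tol) break
    V <- -Uv
  }
  if (res > tol) {
    msg <- sprintf(
      "field inversion did not converge: residual %.4g mm > tol %.4g mm after %d iterations",
      res, tol, maxIter)
    if (diffeo) stop(msg) else warning(msg)
  }
  conv <- if (fieldConvention(u) == "resampling") "forward" else "resampling"
  vectorField(array(V, d), affine = imgAffine(u), convention = conv)
}

# Separable Gaussian smoothing ------------------------------------------------

.gaussKernelMat <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- g[ok]
  }
  # renormalized (truncated) kernel: constants are preserved, incl. at edges
  K / rowSums(K)
}

#' Separable Gaussian smoothing of a 3-D or 4-D array
#'
#' Truncated (3 sigma) renormalized kernel applied along each axis; the last
#' dimension of a 4-D array is treated as components.  Constant arrays are
#' reproduced exactly, including at the boundary.
#'
#' @param arr 3-D or 4-D numeric array.
#' @param sigma Gaussian sigma in voxels; 0 returns the input.
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  if (length(d) == 4L) {
    for (c in seq_len(d[4]))
      arr[, , , c] <- gaussianSmooth(array(arr[, , , c], d[1:3]), sigma)
    return(arr)
  }
  K1 <- .gaussKernelMat(d[1], sigma)
  a <- array(K1 %*% matrix(arr, d[1]), d)
  K2t <- t(.gaussKernelMat(d[2], sigma))
  for (k in seq_len(d[3])) a[, , k] <- a[, , k] %*% K2t
  array(matrix(a, d[1] * d[2]) %*% t(.gaussKernelMat(d[3], sigma)), d)
}
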