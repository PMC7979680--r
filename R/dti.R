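# Diffusion-tensor eigen-analysis, fractional anisotropy, nearest-voxel
# fiber mapping onto mesh elements, and deterministic streamline tracking.

#' Construct a TensorVolume
#'
#' @param data 4-D array \code{c(nx, ny, nz, 6)}; component order Dxx, Dxy,
#'   Dxz, Dyy, Dyz, Dzz.
#' @param affine 4x4 voxel-to-world matrix; alternatively \code{spacing} and
#'   \code{origin}.
#' @param spacing,origin used when \code{affine} is missing.
#' @return a [TensorVolume-class].
#' @export
tensorVolume <- function(data, affine = NULL, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  if (is.null(affine)) affine <- affineFromSpacing(spacing, origin)
  new("TensorVolume", data = data, affine = affine)
}

.tensorFromSix <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3L, 3L)
}

.sixFromTensor <- function(D) {
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

#' Eigen-decomposition of a symmetric diffusion tensor
#'
#' Returns descending eigenvalues and a right-handed orthonormal eigenvector
#' basis.  The sign of the first eigenvector is canonicalized so that its
#' largest-magnitude component is nonnegative (the fiber direction is an
#' axis, not a vector; canonicalization makes the output deterministic).
#'
#' @param D symmetric 3x3 matrix (asymmetry beyond 1e-8 is an error).
#' @return list with \code{values} (length 3, descending) and \code{vectors}
#'   (3x3, columns v1, v2, v3, right-handed).
#' @export
tensorEigen <- function(D) {
  if (max(abs(D - t(D))) > 1e-8)
    stop("tensor is not symmetric (asymmetry ",
         format(max(abs(D - t(D)))), ")")
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE)   # descending by default
  V <- ev$vectors
  for (c0 in 1:2) {
    k <- which.max(abs(V[, c0]))
    if (V[k, c0] < 0) V[, c0] <- -V[, c0]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  list(values = ev$values, vectors = V)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' \code{FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||}: 0 for an
#' isotropic tensor, 1 for a rank-one tensor.  Negative eigenvalues (noise)
#' are clipped at zero with a warning; an all-zero triple is defined as FA 0
#' with a warning.
#'
#' @param lambda numeric vector of 3 eigenvalues (or a matrix with 3 columns
#'   for the vectorized form).
#' @return FA in [0, 1].
#' @export
fractionalAnisotropy <- function(lambda) {
  L <- if (is.matrix(lambda)) lambda else matrix(lambda, ncol = 3L)
  if (any(L < 0)) {
    warning(sum(L < 0), " negative eigenvalue(s) clipped at 0")
    L[L < 0] <- 0
  }
  nrm2 <- rowSums(L^2)
  zero <- nrm2 == 0
  if (any(zero)) warning(sum(zero), " all-zero eigenvalue triple(s); FA set to 0")
  mu <- rowMeans(L)
  dev2 <- rowSums((L - mu)^2)
  fa <- ifelse(zero, 0, sqrt(1.5 * dev2 / pmax(nrm2, 1e-300)))
  fa <- pmin(fa, 1)
  if (is.matrix(lambda)) fa else fa[1L]
}

# FA and first eigenvector for a block of 6-component tensors (n x 6).
.faV1Block <- function(six) {
  n <- nrow(six)
  fa <- numeric(n)
  v1 <- matrix(0, n, 3L)
  negs <- 0L
  for (i in seq_len(n)) {
    ev <- eigen(.tensorFromSix(six[i, ]), symmetric = TRUE)
    lam <- ev$values
    negs <- negs + sum(lam < 0)
    lam[lam < 0] <- 0
    nrm2 <- sum(lam^2)
    fa[i] <- if (nrm2 == 0) 0 else
      min(1, sqrt(1.5 * sum((lam - mean(lam))^2) / nrm2))
    v <- ev$vectors[, 1]
    k <- which.max(abs(v))
    v1[i, ] <- if (v[k] < 0) -v else v
  }
  if (negs) warning(negs, " negative eigenvalue(s) clipped at 0")
  deg <- rowSums(v1^2) == 0
  v1[deg, 1] <- 1
  list(fa = fa, v1 = v1)
}

#' Map diffusion-tensor information onto mesh elements
#'
#' For each element, the tensor voxel closest to the element centroid (in
#' world coordinates, ties to the lowest linear index) provides the FA and
#' first principal eigenvector linked to that element.  Centroids outside
#' the tensor volume get FA 0 and the x axis, with a warning count.
#'
#' @param mesh a [HexMesh-class].
#' @param tensors a [TensorVolume-class].
#' @return an [ElementFiberMap-class].
#' @export
mapDtiToElements <- function(mesh, tensors) {
  d <- dim(imgData(tensors))
  ctr <- worldToVoxel(imgAffine(tensors), elementCentroids(mesh))
  inside <- ctr[, 1] >= -0.5 & ctr[, 1] <= d[1] - 0.5 &
            ctr[, 2] >= -0.5 & ctr[, 2] <= d[2] - 0.5 &
            ctr[, 3] >= -0.5 & ctr[, 3] <= d[3] - 0.5
  m <- nrow(ctr)
  fa <- numeric(m)
  v1 <- matrix(rep(c(1, 0, 0), each = m), m, 3L)
  if (any(inside)) {
    lin <- .sampleNearestIdx(ctr[inside, , drop = FALSE], d[1:3])
    nvox <- prod(d[1:3])
    six <- sapply(0:5, function(c0) imgData(tensors)[lin + c0 * nvox])
    six <- matrix(six, ncol = 6L)
    res <- .faV1Block(six)
    fa[inside] <- res$fa
    v1[inside, ] <- res$v1
  }
  if (any(!inside))
    warning(sum(!inside), " element centroid(s) outside the tensor volume; ",
            "FA 0 and x-axis direction assigned")
  new("ElementFiberMap", fa = fa, v1 = v1, outsideCount = sum(!inside))
}

# Interpolated tensor -> (FA, v1) at arbitrary world points.  Interpolating
# the 6 tensor components (not the eigenvectors) sidesteps the eigenvector
# sign ambiguity and yields a smooth direction field.
.tensorAt <- function(tensors, pts) {
  six <- sampleTrilinear(tensors, pts, outside = "clamp")
  .faV1Block(six)
}

#' Deterministic streamline tractography
#'
#' Bidirectional Euler integration along the first principal eigenvector of
#' the (trilinearly interpolated) tensor field, with sign continuity: at each
#' step the eigenvector sign making the dot product with the previous
#' direction positive is chosen.  A line terminates when FA drops below
#' \code{faStop}, the turning angle exceeds \code{angleStop}, the point
#' leaves the volume, or \code{maxPoints} is reached (per direction).
#'
#' @param tensors a [TensorVolume-class].
#' @param seeds N x 3 matrix of seed points, world mm.  Seeds below the FA
#'   threshold are skipped; no valid seed yields an empty set with a warning.
#' @param step Euler step length, mm.
#' @param faStop FA termination threshold.
#' @param angleStop turning-angle threshold, degrees.
#' @param maxPoints cap on points per direction.
#' @return a [FiberSet-class].
#' @export
trackStreamlines <- function(tensors, seeds, step = 0.5, faStop = 0.2,
                             angleStop = 45, maxPoints = 2000L) {
  seeds <- rbind3(seeds)
  d <- dim(imgData(tensors))[1:3]
  cosStop <- cos(angleStop * pi / 180)
  insideP <- function(p) {
    v <- worldToVoxel(imgAffine(tensors), matrix(p, 1L))
    all(v >= -0.5) && all(v <= d - 0.5)
  }
  lines <- list(); seedId <- integer(0); meanFa <- numeric(0)
  for (si in seq_len(nrow(seeds))) {
    p0 <- seeds[si, ]
    if (!insideP(p0)) next
    t0 <- .tensorAt(tensors, matrix(p0, 1L))
    if (t0$fa[1] < faStop) next
    half <- function(sgn) {
      p <- p0
      dir <- sgn * t0$v1[1, ]
      pts <- matrix(p, 1L)
      fas <- t0$fa[1]
      for (k in seq_len(maxPoints - 1L)) {
        pn <- p + step * dir
        if (!insideP(pn)) break
        tn <- .tensorAt(tensors, matrix(pn, 1L))
        if (tn$fa[1] < faStop) break
        dn <- tn$v1[1, ]
        if (sum(dn * dir) < 0) dn <- -dn     # sign continuity
        if (sum(dn * dir) < cosStop) break   # curvature stop
        p <- pn; dir <- dn
        pts <- rbind(pts, p)
        fas <- c(fas, tn$fa[1])
      }
      list(pts = pts, fas = fas)
    }
    fwd <- half(1); bwd <- half(-1)
    pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts)))[-nrow(bwd$pts)], ,
                         drop = FALSE], fwd$pts)
    lines[[length(lines) + 1L]] <- unname(pts)
    seedId <- c(seedId, si)
    meanFa <- c(meanFa, mean(c(rev(bwd$fas[-1]), fwd$fas)))
  }
  if (!length(lines))
    warning("no valid seeds above the FA threshold; empty fiber set")
  new("FiberSet", lines = lines, seedId = seedId, meanFa = meanFa,
      step = step)
}
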