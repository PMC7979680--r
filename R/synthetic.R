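# Synthetic fixtures with closed-form ground truth: ellipsoid head phantoms
# with nested labeled subregions, analytic diffeomorphic warps, hexahedral
# lattices, tensor fields with prescribed principal directions, and modal
# impact motion histories with known strain peaks.  Every generator is a
# pure function of its spec and seed.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Specification of an ellipsoid head phantom
#'
#' Geometry is ellipsoid-based so that every downstream ground truth
#' (volumes, overlaps, warps) stays closed-form.  The cranial mask is a
#' filled ellipsoid (the intracranial space), the brain a concentric smaller
#' ellipsoid, and the labeled subregions (white matter, corpus callosum,
#' brain stem, hippocampus, thalamus, cerebellum, ventricles) nested
#' ellipsoids painted in order inside it.  A thin bright shell outside the
#' cranial ellipsoid stands in for the skull so that skull stripping is a
#' real operation.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing, mm.
#' @param cranialRadii ellipsoid semi-axes of the intracranial space, mm.
#' @param csfGap gap between cranial and brain ellipsoids, mm.
#' @param noiseSd additive Gaussian noise SD (intensity units); requires a
#'   seed when positive.
#' @param seed RNG seed for the noise.
#' @param scale overall isotropic size factor (1 = the default head; the
#'   published size range of smallest to largest adult intracranial volume,
#'   a factor of about 2.6 in volume, corresponds to scale about 1.37).
#' @return a list spec for [makeHeadPhantom()].
#' @export
headPhantomSpec <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                            cranialRadii = c(26, 22, 20) * scale,
                            csfGap = 3 * scale, noiseSd = 0, seed = NULL,
                            scale = 1) {
  list(shape = as.integer(shape), spacing = spacing,
       cranialRadii = cranialRadii, csfGap = csfGap,
       noiseSd = noiseSd, seed = seed)
}

# label -> representative T1-like intensity
.phantomIntensities <- c(skull = 200, csf = 30, cerebralGM = 80,
                         cerebralWM = 120, CC = 130, BS = 110,
                         hippocampus = 85, thalamus = 95, cerebellum = 75,
                         ventricles = 30)

#' Generate an ellipsoid head phantom
#'
#' Produces a T1-like intensity image (piecewise-constant per label,
#' Gaussian-smoothed with sigma 1 voxel, plus seeded additive noise), exact
#' binary cranial and brain masks (pre-noise geometry), and an integer
#' region-label volume using the [regionCodes()] vocabulary.  Deterministic
#' given the spec.  Violated nesting (any labeled voxel outside the brain, or
#' brain voxel outside the cranial mask) is an error.
#'
#' @param spec a [headPhantomSpec()] list.
#' @return list with \code{t1}, \code{cranialMask}, \code{brainMask},
#'   \code{labels} ([ImageVolume-class]) and \code{icv} (analytic
#'   intracranial volume, ml).
#' @export
makeHeadPhantom <- function(spec = headPhantomSpec()) {
  if (spec$noiseSd > 0 && is.null(spec$seed))
    stop("a seed is mandatory for noisy phantom output")
  d <- spec$shape
  affine <- affineFromSpacing(spec$spacing)
  P <- gridWorldCoords(d, affine)
  ctr <- (d - 1) * spec$spacing / 2
  rc <- spec$cranialRadii
  rb <- rc - spec$csfGap
  if (any(rb <= 0)) stop("nesting violation: brain radii must be positive")
  inEll <- function(c0, r0) {
    q <- ((P[, 1] - ctr[1] - c0[1]) / r0[1])^2 +
         ((P[, 2] - ctr[2] - c0[2]) / r0[2])^2 +
         ((P[, 3] - ctr[3] - c0[3]) / r0[3])^2
    q <= 1
  }
  cranial <- inEll(c(0, 0, 0), rc)
  brain <- inEll(c(0, 0, 0), rb)
  skull <- inEll(c(0, 0, 0), rc + 2.5) & !cranial
  codes <- regionCodes()
  lab <- integer(nrow(P))
  lab[brain] <- codes[["cerebralGM"]]
  paint <- function(lab, name, c0, r0) {
    sel <- inEll(c0 * rb, r0 * rb)
    if (any(sel & !brain))
      stop("nesting violation: region '", name,
           "' extends outside the brain ellipsoid")
    lab[sel] <- codes[[name]]
    lab
  }
  lab <- paint(lab, "cerebralWM", c(0, 0, 0), c(0.78, 0.78, 0.78))
  lab <- paint(lab, "cerebellum", c(0, -0.42, -0.42), c(0.22, 0.22, 0.22))
  lab <- paint(lab, "BS", c(0, -0.15, -0.52), c(0.14, 0.14, 0.32))
  lab <- paint(lab, "CC", c(0, 0, 0.38), c(0.16, 0.5, 0.1))
  lab <- paint(lab, "thalamus", c(0.28, 0, 0.02), c(0.16, 0.16, 0.16))
  lab <- paint(lab, "thalamus", c(-0.28, 0, 0.02), c(0.16, 0.16, 0.16))
  lab <- paint(lab, "hippocampus", c(0.45, -0.3, -0.12), c(0.12, 0.26, 0.12))
  lab <- paint(lab, "hippocampus", c(-0.45, -0.3, -0.12), c(0.12, 0.26, 0.12))
  lab <- paint(lab, "ventricles", c(0.13, 0.08, 0.16), c(0.09, 0.32, 0.13))
  lab <- paint(lab, "ventricles", c(-0.13, 0.08, 0.16), c(0.09, 0.32, 0.13))

  inten <- numeric(nrow(P))
  inten[skull] <- .phantomIntensities[["skull"]]
  inten[cranial & !brain] <- .phantomIntensities[["csf"]]
  for (nm in setdiff(names(codes), "background")) {
    sel <- lab == codes[[nm]]
    if (any(sel)) inten[sel] <- .phantomIntensities[[nm]]
  }
  t1arr <- gaussianSmooth(array(inten, d), 1)
  t1arr <- .withSeed(spec$seed, {
    if (spec$noiseSd > 0)
      t1arr + array(stats::rnorm(length(t1arr), 0, spec$noiseSd), d)
    else t1arr
  })
  list(
    t1 = imageVolume(t1arr, affine = affine),
    cranialMask = imageVolume(array(as.numeric(cranial), d), affine = affine,
                              isMask = TRUE),
    brainMask = imageVolume(array(as.numeric(brain), d), affine = affine,
                            isMask = TRUE),
    labels = imageVolume(array(as.numeric(lab), d), affine = affine),
    icv = 4 / 3 * pi * prod(rc) / 1000)
}

#' Analytic diffeomorphic warps with closed-form evaluators
#'
#' Builds a displacement field (resampling convention: a synthetic subject is
#' \code{warpImage(baseline, field)}) together with its exact functional form
#' and an exact inverse evaluator for ground-truth comparisons.  The
#' amplitude is bounded per kind so that the analytic Jacobian determinant of
#' \code{id + u} stays at or above 0.2 everywhere (an operator-norm bound
#' \code{r} on the displacement gradient guarantees
#' \code{det >= (1 - r)^3}); a violating amplitude is an error.
#'
#' Kinds: \code{"affine"} (\code{u = amplitude * (A0 x' + b0)} with fixed
#' unit patterns about the grid centre), \code{"sinusoid"} (cyclic
#' cross-axis sine displacements of wavelength equal to the grid extent),
#' \code{"radial"} (Gaussian radial bulge, amplitude in strain units).
#'
#' @param kind \code{"affine"}, \code{"sinusoid"} or \code{"radial"}.
#' @param amplitude mm for affine/sinusoid; dimensionless peak radial strain
#'   for radial.
#' @param grid an [ImageVolume-class] (or any object with data dims and
#'   affine) defining the output grid.
#' @return list with \code{field} ([VectorField-class]), \code{evaluate}
#'   (function of N x 3 world points returning displacements), \code{inverse}
#'   (exact inverse of \code{id + u} by contraction iteration, tol 1e-12 mm)
#'   and \code{jacobianLowerBound}.
#' @export
makeWarp <- function(kind = c("affine", "sinusoid", "radial"), amplitude,
                     grid) {
  kind <- match.arg(kind)
  d <- dim(imgData(grid))[1:3]
  affine <- imgAffine(grid)
  ext <- (d - 1) * voxelSpacing(affine)
  ctr <- voxelToWorld(affine, matrix((d - 1) / 2, 1L))[1, ]
  rmax <- 1 - 0.2^(1 / 3)          # operator-norm bound giving det >= 0.2
  if (kind == "affine") {
    A0 <- matrix(c(0.04, 0.01, 0, 0.01, -0.03, 0.005, 0, 0.005, 0.02), 3L, 3L)
    b0 <- c(1, -0.5, 0.8)
    A <- amplitude * A0
    dj <- det(diag(3) + A)
    if (dj < 0.2)
      stop(sprintf("affine warp amplitude %.3g gives det(I+A) = %.3f < 0.2",
                   amplitude, dj))
    evalFun <- function(pts) {
      pts <- rbind3(pts)
      sweep(pts, 2L, ctr) %*% t(A) +
        matrix(amplitude * b0, nrow(pts), 3L, byrow = TRUE)
    }
    bound <- dj
  } else if (kind == "sinusoid") {
    L <- ext
    gmax <- abs(amplitude) * 2 * pi / min(L)
    if (gmax > rmax)
      stop(sprintf(
        "sinusoid amplitude %.3g mm exceeds the diffeomorphism bound %.3g mm",
        amplitude, rmax * min(L) / (2 * pi)))
    evalFun <- function(pts) {
      pts <- rbind3(pts)
      cbind(amplitude * sin(2 * pi * (pts[, 2] - ctr[2]) / L[2]),
            amplitude * sin(2 * pi * (pts[, 3] - ctr[3]) / L[3]),
            amplitude * sin(2 * pi * (pts[, 1] - ctr[1]) / L[1]))
    }
    bound <- (1 - gmax)^3
  } else {
    sig <- min(ext) / 6
    if (abs(amplitude) > rmax)
      stop(sprintf(
        "radial warp amplitude %.3g exceeds the diffeomorphism bound %.3g",
        amplitude, rmax))
    evalFun <- function(pts) {
      pts <- rbind3(pts)
      cc <- sweep(pts, 2L, ctr)
      rho2 <- rowSums(cc^2)
      amplitude * exp(-rho2 / (2 * sig^2)) * cc
    }
    bound <- (1 - abs(amplitude))^3
  }
  if (amplitude == 0) evalFun <- function(pts) {
    pts <- rbind3(pts); matrix(0, nrow(pts), 3L)
  }
  P <- gridWorldCoords(d, affine)
  field <- vectorField(array(evalFun(P), c(d, 3L)), affine = affine,
                       convention = "resampling")
  invFun <- function(pts) {           # solve (id + u)(x) = y for x
    pts <- rbind3(pts)
    X <- pts
    for (k in 1:200) {
      Xn <- pts - evalFun(X)
      if (max(abs(Xn - X)) < 1e-12) { X <- Xn; break }
      X <- Xn
    }
    X
  }
  list(field = field, evaluate = evalFun, inverse = invFun,
       jacobianLowerBound = bound)
}

#' Axis-aligned hexahedral lattice
#'
#' \code{nx * ny * nz} unit-quality elements with VTK corner ordering.
#'
#' @param nx,ny,nz element counts per axis (>= 1).
#' @param spacing element edge length(s), mm.
#' @param origin world coordinates of the first node, mm.
#' @return a [HexMesh-class] with all scaled Jacobians equal to 1.
#' @export
makeHexLattice <- function(nx, ny, nz, spacing = 1, origin = c(0, 0, 0)) {
  if (min(nx, ny, nz) < 1L) stop("lattice dimensions must be >= 1")
  sp <- rep(spacing, length.out = 3L)
  gx <- 0:nx * sp[1] + origin[1]
  gy <- 0:ny * sp[2] + origin[2]
  gz <- 0:nz * sp[3] + origin[3]
  nodes <- cbind(rep(gx, times = (ny + 1) * (nz + 1)),
                 rep(rep(gy, each = nx + 1), times = nz + 1),
                 rep(gz, each = (nx + 1) * (ny + 1)))
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  i <- rep(0:(nx - 1), times = ny * nz)
  j <- rep(rep(0:(ny - 1), each = nx), times = nz)
  k <- rep(0:(nz - 1), each = nx * ny)
  elements <- cbind(nid(i, j, k),     nid(i + 1, j, k),
                    nid(i + 1, j + 1, k), nid(i, j + 1, k),
                    nid(i, j, k + 1), nid(i + 1, j, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  hexMesh(nodes, elements)
}

#' Synthetic diffusion-tensor fields with prescribed FA and direction
#'
#' Axially symmetric tensors with unit trace whose eigenvalues are solved in
#' closed form so that \code{FA(lambda) = faTarget}: with
#' \code{delta = FA * sqrt(3 / (9 - 6 FA^2))}, the eigenvalues are
#' \code{(1 + 2 delta) / 3} and twice \code{(1 - delta) / 3}.  Patterns:
#' \code{"uniform"} (first eigenvector along x everywhere) and \code{"arc"}
#' (tangential in-plane directions inside a mid-plane annulus, isotropic
#' outside, emulating the arched fiber geometry of commissural tracts).
#'
#' @param pattern \code{"uniform"} or \code{"arc"}.
#' @param faTarget fractional anisotropy in [0, 1).
#' @param grid an [ImageVolume-class] defining the voxel grid.
#' @param innerRadius,outerRadius annulus radii for the arc pattern, mm
#'   (defaults scale with the grid).
#' @param halfThickness half-thickness of the arc slab along z, mm.
#' @return a [TensorVolume-class].
#' @export
makeTensorField <- function(pattern = c("uniform", "arc"), faTarget, grid,
                            innerRadius = NULL, outerRadius = NULL,
                            halfThickness = NULL) {
  pattern <- match.arg(pattern)
  if (faTarget < 0 || faTarget >= 1) stop("faTarget must lie in [0, 1)")
  d <- dim(imgData(grid))[1:3]
  affine <- imgAffine(grid)
  delta <- faTarget * sqrt(3 / (9 - 6 * faTarget^2))
  l1 <- (1 + 2 * delta) / 3
  l2 <- (1 - delta) / 3
  P <- gridWorldCoords(d, affine)
  n <- nrow(P)
  six <- matrix(0, n, 6L)
  iso <- c(1, 0, 0, 1, 0, 1) / 3
  if (pattern == "uniform") {
    six <- matrix(rep(c(l1, 0, 0, l2, 0, l2), each = n), n, 6L)
  } else {
    ext <- (d - 1) * voxelSpacing(affine)
    ctr <- voxelToWorld(affine, matrix((d - 1) / 2, 1L))[1, ]
    if (is.null(outerRadius)) outerRadius <- 0.42 * min(ext[1:2])
    if (is.null(innerRadius)) innerRadius <- 0.5 * outerRadius
    if (is.null(halfThickness)) halfThickness <- 0.08 * ext[3]
    cc <- sweep(P, 2L, ctr)
    rho <- sqrt(cc[, 1]^2 + cc[, 2]^2)
    inArc <- rho >= innerRadius & rho <= outerRadius &
             abs(cc[, 3]) <= halfThickness & rho > 1e-9
    six <- matrix(rep(iso, each = n), n, 6L)
    if (any(inArc)) {
      tx <- -cc[inArc, 2] / rho[inArc]
      ty <- cc[inArc, 1] / rho[inArc]
      dl <- l1 - l2
      six[inArc, ] <- cbind(l2 + dl * tx^2, dl * tx * ty, 0,
                            l2 + dl * ty^2, 0, rep(l2, sum(inArc)))
    }
  }
  tensorVolume(array(six, c(d, 6L)), affine = affine)
}

#' Modal impact motion with closed-form strain ground truth
#'
#' Applies a smooth raised-cosine temporal envelope \code{s(t)} (zero at the
#' ends, 1 at \code{peakTime}) to an affine spatial mode about the mesh
#' centroid: \code{"stretch"} (uniaxial along x, \code{amplitude} = peak
#' stretch ratio), \code{"shear"} (simple shear of x by y, \code{amplitude} =
#' peak engineering shear), \code{"rotation"} (rigid rotation about z by
#' \code{amplitude} radians, scaled in angle so the motion is rigid at every
#' instant), or \code{"mix"} (the stretch mode composed with a rigid
#' rotation, which leaves the strain of the stretch unchanged by
#' objectivity).  The analytic Green-Lagrange tensor at the peak, the peak
#' first principal strain, and the peak time are returned alongside.
#'
#' @param mesh a [HexMesh-class].
#' @param mode spatial mode, see above.
#' @param peakTime time of peak deformation, ms.
#' @param amplitude mode amplitude (see above).
#' @param duration total duration, ms (default twice the peak time).
#' @param dt output time step, ms.
#' @param noiseSd optional displacement noise SD, mm (requires seed).
#' @param seed RNG seed for the noise.
#' @return list with \code{motion} ([NodalHistory-class]) and
#'   \code{analytic}: \code{E6} (tensor at peak, component order as
#'   [StrainHistory-class]), \code{mps}, \code{time}, and \code{mas}, a
#'   function of a unit fiber direction.
#' @export
makeImpactHistory <- function(mesh, mode = c("stretch", "shear", "rotation",
                                             "mix"),
                              peakTime = 36, amplitude, duration = NULL,
                              dt = 4, noiseSd = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (noiseSd > 0 && is.null(seed))
    stop("a seed is mandatory for noisy motion output")
  if (is.null(duration)) duration <- 2 * peakTime
  times <- seq(0, duration, by = dt)
  if (!any(abs(times - peakTime) < 1e-9))
    stop("dt must divide peakTime so the peak frame is sampled")
  if (abs(duration - 2 * peakTime) > 1e-9)
    stop("duration must equal twice the peak time (symmetric envelope)")
  s <- sin(pi * times / duration)^2   # raised cosine, peak 1 at duration/2
  nodes <- meshNodes(mesh)
  ctr <- colMeans(nodes)
  cc <- sweep(nodes, 2L, ctr)
  Fmat <- function(sv) {
    switch(mode,
      stretch = diag(c(1 + sv * (amplitude - 1), 1, 1)),
      shear = {
        M <- diag(3); M[1, 2] <- sv * amplitude; M
      },
      rotation = {
        th <- sv * amplitude
        M <- diag(3)
        M[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
        M
      },
      mix = {
        th <- sv * pi / 6
        R <- diag(3)
        R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
        R %*% diag(c(1 + sv * (amplitude - 1), 1, 1))
      })
  }
  nt <- length(times)
  disp <- array(0, c(nrow(nodes), 3L, nt))
  for (ti in seq_len(nt))
    disp[, , ti] <- cc %*% t(Fmat(s[ti])) - cc
  disp <- .withSeed(seed, {
    if (noiseSd > 0) {
      nz <- array(stats::rnorm(length(disp), 0, noiseSd), dim(disp))
      nz[, , 1] <- 0
      disp + nz
    } else disp
  })
  Fp <- Fmat(1)
  Ep <- (t(Fp) %*% Fp - diag(3)) / 2
  E6 <- c(Ep[1, 1], Ep[2, 2], Ep[3, 3], Ep[1, 2], Ep[2, 3], Ep[1, 3])
  list(motion = nodalHistory(times, disp),
       analytic = list(
         E6 = E6,
         mps = eigen(Ep, symmetric = TRUE, only.values = TRUE)$values[1],
         time = peakTime,
         mas = function(v) as.numeric(v %*% Ep %*% v)))
}
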