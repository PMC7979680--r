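# Hierarchical registration: rigid principal-axes alignment, diffeomorphic
# demons, skull stripping, and the two-stage personalization pipeline that
# morphs a baseline hexahedral head mesh onto a subject.

#' Demons settings constructor
#'
#' Defaults: pyramid (4, 2, 1), iterations (100, 50, 20), update sigma 1.0
#' voxel, field sigma 1.5 voxels, step cap 2.0 voxels, at least 4
#' scaling-and-squaring steps.  The deformable stages of the published
#' pipeline inherit their parameters from external registration software;
#' these defaults are this package's own calibration, chosen so that known
#' synthetic warps are recovered, and every one is exposed here.
#'
#' @param pyramidFactors integer downsampling factors, coarse to fine.
#' @param itersPerLevel iteration counts per level.
#' @param sigmaUpdate,sigmaField Gaussian sigmas, voxels.
#' @param maxStep per-iteration force cap, voxels.
#' @param squaringMin minimum scaling-and-squaring steps.
#' @return a [DemonsSettings-class].
#' @export
demonsSettings <- function(pyramidFactors = c(4L, 2L, 1L),
                           itersPerLevel = c(100L, 50L, 20L),
                           sigmaUpdate = 1.0, sigmaField = 1.5,
                           maxStep = 2.0, squaringMin = 4L) {
  new("DemonsSettings", pyramidFactors = as.integer(pyramidFactors),
      itersPerLevel = as.integer(itersPerLevel),
      sigmaUpdate = sigmaUpdate, sigmaField = sigmaField,
      maxStep = maxStep, squaringMin = as.integer(squaringMin))
}

#' Rigid (6-DOF) registration of two binary masks
#'
#' Deterministic centroid + principal-axes alignment: the rotation maps the
#' moving mask's principal axes onto the fixed mask's; among the four proper
#' axis-sign assignments the one maximizing mask overlap is returned, and the
#' translation maps the moving centroid onto the fixed centroid.  For a
#' perfectly spherical mask the rotation is unconstrained (any orthonormal
#' basis is principal); the translation is still exact.
#'
#' @param fixedMask,movingMask non-empty binary [ImageVolume-class] masks.
#' @return a [RigidTransform-class] mapping moving world coordinates onto
#'   fixed world coordinates.
#' @export
rigidRegister <- function(fixedMask, movingMask) {
  stats <- lapply(list(fixedMask, movingMask), function(m) {
    arr <- imgData(m)
    idx <- which(arr > 0.5)
    if (!length(idx)) stop("rigid registration requires non-empty masks")
    d <- dim(arr)
    i <- (idx - 1L) %% d[1]
    j <- ((idx - 1L) %/% d[1]) %% d[2]
    k <- (idx - 1L) %/% (d[1] * d[2])
    pts <- voxelToWorld(imgAffine(m), cbind(i, j, k))
    ctr <- colMeans(pts)
    cc <- sweep(pts, 2L, ctr)
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    U <- ev$vectors
    if (det(U) < 0) U[, 3] <- -U[, 3]
    list(ctr = ctr, U = U, pts = pts)
  })
  f <- stats[[1]]; m <- stats[[2]]
  signs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL; bestScore <- -Inf
  for (s in seq_len(4L)) {
    R <- f$U %*% diag(signs[s, ], 3L) %*% t(m$U)
    t0 <- f$ctr - as.numeric(R %*% m$ctr)
    moved <- applyRigid(rigidTransform(R, t0), m$pts)
    score <- sum(sampleNearest(fixedMask, moved, outside = "clamp"))
    if (score > bestScore) { bestScore <- score; best <- rigidTransform(R, t0) }
  }
  best
}

#' Express a rigid transform as a resampling displacement field
#'
#' Produces the field that, applied with [warpImage()] on \code{grid},
#' resamples the moving image into the fixed frame:
#' \code{u(x) = R^T (x - t) - x}.
#'
#' @param rigid a [RigidTransform-class] (moving to fixed).
#' @param grid an [ImageVolume-class] (or [VectorField-class]) defining the
#'   output grid.
#' @return a resampling [VectorField-class].
#' @export
rigidToField <- function(rigid, grid) {
  d <- dim(imgData(grid))[1:3]
  P <- gridWorldCoords(d, imgAffine(grid))
  U <- applyRigid(rigidInverse(rigid), P) - P
  vectorField(array(U, c(d, 3L)), affine = imgAffine(grid),
              convention = "resampling")
}

# --- demons internals (everything in voxel units of the input grid) ---------

.pyrDown <- function(arr, f) {
  if (f == 1L) return(arr)
  sm <- gaussianSmooth(arr, f / 2)
  d <- dim(sm)
  sm[seq(1L, d[1], by = f), seq(1L, d[2], by = f), seq(1L, d[3], by = f),
     drop = FALSE]
}

# Trilinearly sample a (nx,ny,nz,3) voxel-displacement array at voxel points.
.sampleFieldVox <- function(U, dims, vox) {
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), dims[a] - 1L)
  prep <- .trilinearPrep(vox, dims)
  nvox <- prod(dims)
  cbind(.sampleTrilinearVec(U, prep, 0L),
        .sampleTrilinearVec(U, prep, nvox),
        .sampleTrilinearVec(U, prep, 2L * nvox))
}

.voxId <- function(dims) {
  cbind(rep.int(0:(dims[1] - 1L), dims[2] * dims[3]),
        rep.int(rep(0:(dims[2] - 1L), each = dims[1]), dims[3]),
        rep(0:(dims[3] - 1L), each = dims[1] * dims[2]))
}

# Exponential of a stationary velocity field by scaling and squaring.
.expVelocity <- function(V, dims, squaringMin) {
  mx <- max(sqrt(rowSums(V^2)))
  N <- max(squaringMin, ceiling(log2(max(mx, 1e-12) / 0.5)))
  U <- V / 2^N
  id <- .voxId(dims)
  for (i in seq_len(N)) U <- U + .sampleFieldVox(U, dims, id + U)
  U
}

.centralGrad <- function(arr) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (a in 1:3) {
    up <- arr; dn <- arr
    n <- d[a]
    idx1 <- c(2:n, n); idx0 <- c(1L, 1:(n - 1L))
    if (a == 1L) { up <- arr[idx1, , , drop = FALSE]; dn <- arr[idx0, , , drop = FALSE] }
    if (a == 2L) { up <- arr[, idx1, , drop = FALSE]; dn <- arr[, idx0, , drop = FALSE] }
    if (a == 3L) { up <- arr[, , idx1, drop = FALSE]; dn <- arr[, , idx0, drop = FALSE] }
    g[[a]] <- as.numeric(up - dn) / 2
  }
  g
}

.demonsCore <- function(fixedArr, movingArr, s) {
  nlev <- length(s@pyramidFactors)
  V <- NULL          # velocity in voxel units of the current level's grid
  dimsPrev <- NULL
  trace <- vector("list", nlev)
  for (lev in seq_len(nlev)) {
    f <- s@pyramidFactors[lev]
    fx <- .pyrDown(fixedArr, f)
    mv <- .pyrDown(movingArr, f)
    dims <- dim(fx)
    id <- .voxId(dims)
    if (is.null(V)) {
      V <- matrix(0, prod(dims), 3L)
    } else {
      # resample velocity from the coarser level: positions rescale by the
      # factor ratio, displacement values convert to this level's voxels
      fPrev <- s@pyramidFactors[lev - 1L]
      V <- .sampleFieldVox(array(V, c(dimsPrev, 3L)), dimsPrev,
                           id * (f / fPrev)) * (fPrev / f)
    }
    grad <- .centralGrad(fx)          # intensity per level voxel
    G1 <- grad[[1]]; G2 <- grad[[2]]; G3 <- grad[[3]]
    gm2 <- G1^2 + G2^2 + G3^2
    fxv <- as.numeric(fx)
    ssdTrace <- numeric(0)
    bestV <- V; bestSsd <- Inf
    iters <- s@itersPerLevel[lev]
    for (it in 0:iters) {
      U <- .expVelocity(V, dims, s@squaringMin)
      warped <- .sampleTrilinearVec(
        mv, .trilinearPrep(.clampVox(id + U, dims, "clamp"), dims))
      diffv <- warped - fxv
      ssd <- sum(diffv^2)
      ssdTrace <- c(ssdTrace, ssd)
      if (ssd < bestSsd) { bestSsd <- ssd; bestV <- V }
      if (it == iters) break
      den <- gm2 + diffv^2
      sc <- ifelse(den > 1e-12, -diffv / den, 0)
      D <- cbind(sc * G1, sc * G2, sc * G3)
      mag <- sqrt(rowSums(D^2))
      over <- mag > s@maxStep
      if (any(over)) D[over, ] <- D[over, ] * (s@maxStep / mag[over])
      D <- matrix(gaussianSmooth(array(D, c(dims, 3L)), s@sigmaUpdate),
                  ncol = 3L)
      V <- matrix(gaussianSmooth(array(V + D, c(dims, 3L)), s@sigmaField),
                  ncol = 3L)
    }
    V <- bestV
    trace[[lev]] <- ssdTrace
    if (bestSsd > ssdTrace[1] + 1e-9 * max(1, ssdTrace[1]))
      stop(sprintf(
        "demons: SSD increased over level %d (%.6g -> %.6g); aborting",
        lev, ssdTrace[1], bestSsd))
    dimsPrev <- dims
  }
  fLast <- s@pyramidFactors[nlev]
  if (fLast != 1L) {   # bring the velocity to the full-resolution grid
    dims0 <- dim(fixedArr)
    V <- .sampleFieldVox(array(V, c(dimsPrev, 3L)), dimsPrev,
                         .voxId(dims0) / fLast) * fLast
    dimsPrev <- dims0
  }
  U <- .expVelocity(V, dimsPrev, s@squaringMin)
  list(u = U, trace = trace)
}

#' Diffeomorphic demons registration
#'
#' Multi-resolution intensity demons with a stationary velocity field.  Per
#' level, the classical optical-flow force
#' \code{d = (m(phi) - f) grad(f) / (|grad f|^2 + (m(phi) - f)^2)} is applied
#' against the accumulated velocity, each update capped at \code{maxStep}
#' voxels, Gaussian-smoothed (\code{sigmaUpdate}), accumulated, and the
#' velocity smoothed again (\code{sigmaField}).  The displacement exposed to
#' the caller is the exponential of the velocity via scaling and squaring
#' (with enough squarings that each half-step stays below 0.5 voxel), which
#' keeps the Jacobian determinant of \code{id + u} positive.  The iterate with
#' the lowest sum-of-squared-differences is retained per level, so the final
#' SSD never exceeds the initial one; a level whose SSD cannot be improved at
#' all aborts with diagnostics.
#'
#' @param fixed,moving [ImageVolume-class] objects on the same grid (register
#'   after rigid pre-alignment).  Intensities must be on comparable scales
#'   (the force is invariant to a common rescaling).
#' @param settings a [DemonsSettings-class].
#' @return a [VectorField-class] in the \code{"resampling"} convention with
#'   fixed's grid (\code{warpImage(moving, u)} approximates fixed).  The
#'   attribute \code{"ssdTrace"} carries the per-level SSD traces.
#' @export
demonsRegister <- function(fixed, moving, settings = demonsSettings()) {
  if (!identical(dim(imgData(fixed)), dim(imgData(moving))) ||
      max(abs(imgAffine(fixed) - imgAffine(moving))) > 1e-6)
    stop("demonsRegister requires fixed and moving on the same grid")
  res <- .demonsCore(imgData(fixed), imgData(moving), settings)
  d <- dim(imgData(fixed))
  Umm <- res$u %*% t(imgAffine(fixed)[1:3, 1:3])
  u <- vectorField(array(Umm, c(d, 3L)), affine = imgAffine(fixed),
                   convention = "resampling")
  if (min(jacobianDeterminant(u)) <= 0)
    warning("demons returned a field with non-positive Jacobian determinant")
  attr(u, "ssdTrace") <- res$trace
  u
}

#' Skull strip an image with a brain mask
#'
#' Voxelwise product; the background is exactly zero.
#'
#' @param t1 an [ImageVolume-class].
#' @param brainMask a binary [ImageVolume-class] on the same grid.
#' @return the masked [ImageVolume-class].
#' @export
skullStrip <- function(t1, brainMask) {
  if (!identical(dim(imgData(t1)), dim(imgData(brainMask))) ||
      max(abs(imgAffine(t1) - imgAffine(brainMask))) > 1e-6)
    stop("skullStrip requires image and mask on the same grid")
  imageVolume(imgData(t1) * imgData(brainMask), affine = imgAffine(t1))
}

#' Configuration for the personalization pipeline
#'
#' @param demonsStage1 settings for the cranial-mask demons stage.
#' @param demonsStage2 settings for the skull-stripped intensity stage.
#' @param composeMode \code{"compose"} (true composition, default) or
#'   \code{"sum"} (literal voxelwise addition of the two stage fields).
#' @param stage2Field optional imported [VectorField-class] (e.g. the output
#'   of an external attribute-matching registration) substituted for the
#'   built-in stage-2 demons.
#' @param qualityFloor minimum-scaled-Jacobian gate for the morphed mesh.
#' @param maskSigma Gaussian sigma (voxels) softening the binary cranial
#'   masks before stage-1 demons; boundary forces then have capture range.
#' @return a list of settings for [personalize()].
#' @export
personalizeConfig <- function(demonsStage1 = demonsSettings(),
                              demonsStage2 = demonsSettings(),
                              composeMode = "compose",
                              stage2Field = NULL,
                              qualityFloor = 0.2,
                              maskSigma = 1.0) {
  list(demonsStage1 = demonsStage1, demonsStage2 = demonsStage2,
       composeMode = composeMode, stage2Field = stage2Field,
       qualityFloor = qualityFloor, maskSigma = maskSigma)
}

#' Hierarchical personalization: morph a baseline head model onto a subject
#'
#' Executes the full pipeline on the baseline grid: (1) rigid principal-axes
#' alignment of the subject onto the baseline; (2) stage-1 diffeomorphic
#' demons between the (softened) cranial masks, giving field 1; (3) the
#' baseline T1 is warped through field 1 and both images are skull stripped;
#' (4) stage-2 intensity demons between the stripped images (or an imported
#' external field), giving field 2; (5) the two resampling fields are
#' combined (true composition by default: the image lookup passes through
#' field 2 then field 1); (6) the combined field is numerically inverted to a
#' forward field which morphs the baseline mesh; (7) the morphed mesh is
#' quality-gated, the warped T1 produced, and DICE computed against the
#' subject's masks (and region labels when provided).
#'
#' A quality-gate failure is reported in the result (\code{pass = FALSE}),
#' not raised as an error.
#'
#' @param baseline list with \code{t1}, \code{cranialMask}, \code{brainMask}
#'   ([ImageVolume-class]), \code{mesh} ([HexMesh-class]) and optionally
#'   \code{labels} (integer region-label volume).
#' @param subject list with \code{t1}, \code{cranialMask}, \code{brainMask}
#'   and optionally \code{labels}.
#' @param cfg a [personalizeConfig()] list.
#' @return a [PersonalizationResult-class].
#' @export
personalize <- function(baseline, subject, cfg = personalizeConfig()) {
  grid <- baseline$t1
  rigid <- rigidRegister(baseline$cranialMask, subject$cranialMask)
  urig <- rigidToField(rigid, grid)
  subjT1 <- warpImage(subject$t1, urig, "linear")
  subjCranial <- warpImage(subject$cranialMask, urig, "nearest")
  subjBrain <- warpImage(subject$brainMask, urig, "nearest")
  subjLabels <- if (!is.null(subject$labels))
    warpImage(subject$labels, urig, "nearest")

  soften <- function(mask) {
    imageVolume(gaussianSmooth(imgData(mask), cfg$maskSigma),
                affine = imgAffine(mask))
  }
  field1 <- demonsRegister(soften(subjCranial), soften(baseline$cranialMask),
                           cfg$demonsStage1)
  warpedT1a <- warpImage(baseline$t1, field1, "linear")
  warpedCranialA <- warpImage(baseline$cranialMask, field1, "nearest")
  # strip with the intracranial (cranial) mask: the stripped images then keep
  # the CSF-skull edge, so stage 2 has data support right up to the cranial
  # surface and cannot drift the alignment stage 1 established there
  strippedBase <- skullStrip(warpedT1a, warpedCranialA)
  strippedSubj <- skullStrip(subjT1, subjCranial)

  field2 <- if (!is.null(cfg$stage2Field)) cfg$stage2Field
            else demonsRegister(strippedSubj, strippedBase, cfg$demonsStage2)

  fieldTotal <- if (cfg$composeMode == "sum")
    composeFields(field1, field2, mode = "sum")
  else
    composeFields(field2, field1, mode = "compose", outside = "clamp")

  warpedT1 <- warpImage(baseline$t1, fieldTotal, "linear")
  forward <- invertField(fieldTotal)
  morphed <- morphMesh(baseline$mesh, forward)
  quality <- qualityReport(morphed, floor = cfg$qualityFloor)

  dice <- c(
    cranial = diceCoefficient(warpImage(baseline$cranialMask, fieldTotal,
                                        "nearest"), subjCranial),
    brain = diceCoefficient(warpImage(baseline$brainMask, fieldTotal,
                                      "nearest"), subjBrain))
  if (!is.null(subjLabels) && !is.null(baseline$labels)) {
    warpedLabels <- warpImage(baseline$labels, fieldTotal, "nearest")
    codes <- sort(setdiff(unique(c(imgData(warpedLabels),
                                   imgData(subjLabels))), 0))
    for (cd in codes) {
      a <- imageVolume((imgData(warpedLabels) == cd) * 1,
                       affine = imgAffine(warpedLabels), isMask = TRUE)
      b <- imageVolume((imgData(subjLabels) == cd) * 1,
                       affine = imgAffine(subjLabels), isMask = TRUE)
      dice[paste0("region", cd)] <- diceCoefficient(a, b)
    }
  }

  new("PersonalizationResult", rigid = rigid, field1 = field1,
      field2 = field2, fieldTotal = fieldTotal, warpedT1 = warpedT1,
      morphedMesh = morphed, quality = quality, diceTable = dice,
      ssdTrace = list(stage1 = attr(field1, "ssdTrace"),
                      stage2 = attr(field2, "ssdTrace")))
}
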