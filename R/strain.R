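# Green-Lagrange strain from nodal motion histories, principal and axonal
# strain, and regional peak extraction with element/time localization.

#' Construct a NodalHistory
#'
#' @param times strictly increasing times, ms; the first frame is the zero
#'   reference configuration.
#' @param displacements array \code{c(nNodes, 3, nTimes)}, mm.
#' @return a [NodalHistory-class].
#' @export
nodalHistory <- function(times, displacements) {
  new("NodalHistory", times = times, displacements = displacements)
}

#' Construct a StrainHistory
#'
#' @param times strictly increasing times, ms.
#' @param tensors array \code{c(nElements, 6, nTimes)}; component order Exx,
#'   Eyy, Ezz, Exy, Eyz, Ezx, tensor shear (Exy = gamma/2).
#' @return a [StrainHistory-class].
#' @export
strainHistory <- function(times, tensors) {
  new("StrainHistory", times = times, tensors = tensors)
}

# Gradients of the 8 trilinear shape functions w.r.t. natural coordinates at
# the element centre (xi = eta = zeta = 0), VTK corner ordering.
.shapeGradCentre <- local({
  sgn <- matrix(c(-1, -1, -1,   1, -1, -1,   1, 1, -1,  -1, 1, -1,
                  -1, -1,  1,   1, -1,  1,   1, 1,  1,  -1, 1,  1),
                ncol = 3L, byrow = TRUE)
  sgn / 8
})

#' Green-Lagrange strain history from nodal motion
#'
#' The deformation gradient is evaluated at each element centroid from the
#' trilinear shape-function gradients of the reference configuration:
#' \code{F = I + du/dX}, \code{E = (F'F - I) / 2}.  Single-point (centroid)
#' evaluation matches common solver element output; the result is exact for
#' affine motions and identically zero for rigid motions (objectivity).
#'
#' @param mesh a [HexMesh-class] (reference configuration).
#' @param motion a [NodalHistory-class] covering all mesh nodes.
#' @return a [StrainHistory-class].
#' @export
elementStrainHistory <- function(mesh, motion) {
  el <- meshElements(mesh)
  if (dim(motion@displacements)[1] < nrow(meshNodes(mesh)))
    stop("motion does not cover all mesh nodes")
  m <- nrow(el)
  nt <- length(motion@times)
  # per-element reference Jacobian and shape gradients w.r.t. X (m x 8 x 3)
  X <- .elementCornerArray(mesh)
  G <- array(0, c(m, 8L, 3L))
  for (e in seq_len(m)) {
    J <- matrix(0, 3L, 3L)                    # dX/dxi
    for (c0 in 1:8) J <- J + X[e, c0, ] %o% .shapeGradCentre[c0, ]
    dj <- det(J)
    if (abs(dj) < 1e-30)
      stop("singular reference element ", e)
    Jinv <- solve(J)
    G[e, , ] <- .shapeGradCentre %*% Jinv     # dN/dX rows
  }
  tensors <- array(0, c(m, 6L, nt))
  for (ti in seq_len(nt)) {
    U <- motion@displacements[, , ti]
    # H = du/dX per element: H[e, a, b] = sum_c U[el[e,c], a] * G[e, c, b]
    H <- array(0, c(m, 3L, 3L))
    for (c0 in 1:8) {
      Uc <- U[el[, c0], , drop = FALSE]
      for (a in 1:3) for (b in 1:3)
        H[, a, b] <- H[, a, b] + Uc[, a] * G[, c0, b]
    }
    # E = (H + H' + H'H) / 2
    E <- array(0, c(m, 3L, 3L))
    for (a in 1:3) for (b in a:3) {
      hh <- H[, 1, a] * H[, 1, b] + H[, 2, a] * H[, 2, b] +
            H[, 3, a] * H[, 3, b]
      E[, a, b] <- (H[, a, b] + H[, b, a] + hh) / 2
    }
    tensors[, , ti] <- cbind(E[, 1, 1], E[, 2, 2], E[, 3, 3],
                             E[, 1, 2], E[, 2, 3], E[, 1, 3])
  }
  strainHistory(motion@times, tensors)
}

#' First principal value of a symmetric strain tensor
#'
#' @param E symmetric 3x3 matrix, or a length-6 vector (Exx, Eyy, Ezz, Exy,
#'   Eyz, Ezx, tensor shear).
#' @return the largest eigenvalue.
#' @export
principalStrain <- function(E) {
  if (is.matrix(E)) {
    if (max(abs(E - t(E))) > 1e-8) stop("strain tensor must be symmetric")
    return(eigen((E + t(E)) / 2, symmetric = TRUE, only.values = TRUE)$values[1])
  }
  .principalFromSix(matrix(E, 1L))[1L]
}

# Vectorized largest eigenvalue for n x 6 symmetric tensors (analytic,
# trigonometric form; cross-checked against eigen() in the tests).
.principalFromSix <- function(six) {
  a11 <- six[, 1]; a22 <- six[, 2]; a33 <- six[, 3]
  a12 <- six[, 4]; a23 <- six[, 5]; a13 <- six[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
        2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(p2 / 6)
  out <- q            # for p == 0 (isotropic) all eigenvalues equal q
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b23 <- a23[nz] / p[nz]; b13 <- a13[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
            b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detB / 2))
    out[nz] <- q[nz] + 2 * p[nz] * cos(acos(r) / 3)
  }
  out
}

#' Axonal strain: projection of a strain tensor onto a fiber direction
#'
#' \code{eps_axon = v' E v}, the Green-Lagrange strain along the local
#' white-matter fiber direction.  Being a quadratic form, it is invariant to
#' the eigenvector sign ambiguity \code{v -> -v}, and is bounded by the
#' extreme eigenvalues: \code{lambda3 <= eps_axon <= lambda1}.
#'
#' @param E symmetric 3x3 matrix or length-6 component vector (as in
#'   [principalStrain()]).
#' @param v unit direction vector; a non-unit vector (beyond 1e-6) is an
#'   error, never silently normalized.
#' @return the projected strain.
#' @export
axonalStrain <- function(E, v) {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
    stop("fiber direction must be a unit vector (|v| = ",
         format(sqrt(sum(v^2))), ")")
  if (!is.matrix(E)) E <- .tensorFromSixE(E)
  as.numeric(v %*% E %*% v)
}

.tensorFromSixE <- function(sx) {
  matrix(c(sx[1], sx[4], sx[6],
           sx[4], sx[2], sx[5],
           sx[6], sx[5], sx[3]), 3L, 3L)
}

# Vectorized v'Ev for n x 6 tensors and n x 3 unit directions.
.axonalFromSix <- function(six, v) {
  six[, 1] * v[, 1]^2 + six[, 2] * v[, 2]^2 + six[, 3] * v[, 3]^2 +
    2 * (six[, 4] * v[, 1] * v[, 2] + six[, 5] * v[, 2] * v[, 3] +
         six[, 6] * v[, 1] * v[, 3])
}

#' Regional peak strains (MPS / MAS) with localization
#'
#' For each region: the maximum (or stated percentile) of the first principal
#' Green-Lagrange strain over the region's elements and all times (MPS), and
#' the same for the axonal projection (MAS), the latter restricted to regions
#' with coherent fiber orientation (cerebral white matter, corpus callosum,
#' brain stem).  The percentile uses the nearest-rank rule on the
#' distribution of per-element peak values; at 100 it is the plain maximum.
#' Both localizations of the open time-vs-element bookkeeping question are
#' reported: \code{element} and \code{time} locate the peak of the reported
#' element's own history, which for percentile 100 coincides with the global
#' max-over-elements-and-times.  Empty regions are omitted with a warning.
#'
#' @param strains a [StrainHistory-class].
#' @param labels factor of region labels per element (from
#'   [labelElementsByImage()]), or an integer vector of region codes.
#' @param fibers optional [ElementFiberMap-class]; when absent, MAS is not
#'   evaluated.
#' @param percentile percentile of the per-element peak distribution
#'   (default 100 = maximum).
#' @return a data.frame with columns \code{region}, \code{metric},
#'   \code{peak}, \code{element}, \code{time}, \code{percentile}.
#' @export
regionalPeaks <- function(strains, labels, fibers = NULL, percentile = 100) {
  nt <- length(strains@times)
  m <- dim(strains@tensors)[1]
  if (length(labels) != m)
    stop("label count does not match element count")
  if (!is.null(fibers) && length(fiberFa(fibers)) != m)
    stop("fiber map count does not match element count")
  codes <- regionCodes()
  labInt <- if (is.factor(labels)) {
    idx <- match(as.character(labels), names(codes))
    ifelse(is.na(idx), suppressWarnings(as.integer(as.character(labels))),
           codes[idx])
  } else as.integer(labels)
  mps <- matrix(0, m, nt)
  for (ti in seq_len(nt))
    mps[, ti] <- .principalFromSix(matrix(strains@tensors[, , ti], ncol = 6L))
  mas <- NULL
  if (!is.null(fibers)) {
    v <- fiberV1(fibers)
    mas <- matrix(0, m, nt)
    for (ti in seq_len(nt))
      mas[, ti] <- .axonalFromSix(matrix(strains@tensors[, , ti], ncol = 6L), v)
  }
  aniso <- anisotropicRegionCodes()
  rows <- list()
  pick <- function(curves, members) {
    # per-element peak over time, then nearest-rank percentile across elements;
    # ties at the selected value go to the lowest element id
    peaks <- apply(curves[members, , drop = FALSE], 1L, max)
    k <- max(1L, ceiling(percentile / 100 * length(peaks)))
    val <- sort(peaks)[k]
    eLoc <- min(members[peaks == val])
    tLoc <- which.max(curves[eLoc, ])
    list(peak = val, element = eLoc, time = strains@times[tLoc])
  }
  for (rn in setdiff(names(codes), "background")) {
    members <- which(labInt == codes[[rn]])
    if (!length(members)) next
    p <- pick(mps, members)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rn, metric = "MPS", peak = p$peak, element = p$element,
      time = p$time, percentile = percentile)
    if (!is.null(mas) && codes[[rn]] %in% aniso) {
      p <- pick(mas, members)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rn, metric = "MAS", peak = p$peak, element = p$element,
        time = p$time, percentile = percentile)
    }
  }
  present <- unique(labInt[labInt != 0])
  missing <- setdiff(setdiff(codes, 0), present)
  if (length(missing))
    warning("empty region(s) omitted: ",
            paste(names(codes)[match(missing, codes)], collapse = ", "))
  do.call(rbind, rows)
}

# --- CSV I/O for histories ---------------------------------------------------

#' Read / write nodal motion and strain histories as long-format CSV
#'
#' Long format: \code{time, id,} then the component columns (\code{ux, uy,
#' uz} for motion; \code{exx, eyy, ezz, exy, eyz, ezx} for strain).  A JSON
#' header (same basename, \code{.json}) declares units and, for strain, the
#' shear convention: \code{"tensor"} (stored as-is) or \code{"engineering"}
#' (gamma values, halved on import).
#'
#' @param path CSV file path.
#' @return a [NodalHistory-class] / [StrainHistory-class].
#' @export
readNodalHistoryCsv <- function(path) {
  df <- utils::read.csv(path)
  times <- sort(unique(df$time))
  ids <- sort(unique(df$id))
  arr <- array(0, c(length(ids), 3L, length(times)))
  ti <- match(df$time, times); ni <- match(df$id, ids)
  for (c0 in 1:3)
    arr[cbind(ni, c0, ti)] <- df[[c("ux", "uy", "uz")[c0]]]
  nodalHistory(times, arr)
}

#' @rdname readNodalHistoryCsv
#' @param motion a [NodalHistory-class].
#' @export
writeNodalHistoryCsv <- function(motion, path) {
  nt <- length(motion@times)
  n <- dim(motion@displacements)[1]
  df <- data.frame(
    time = rep(motion@times, each = n),
    id = rep(seq_len(n), nt),
    ux = as.numeric(motion@displacements[, 1, ]),
    uy = as.numeric(motion@displacements[, 2, ]),
    uz = as.numeric(motion@displacements[, 3, ]))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(units = list(time = "ms", displacement = "mm")),
                       .csvSidecarPath(path), auto_unbox = TRUE)
  invisible(path)
}

.csvSidecarPath <- function(path) sub("\\.csv$", ".json", path)

#' @rdname readNodalHistoryCsv
#' @export
readStrainHistoryCsv <- function(path) {
  df <- utils::read.csv(path)
  shear <- "tensor"
  side <- .csvSidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$shear)) shear <- meta$shear
  }
  times <- sort(unique(df$time))
  ids <- sort(unique(df$id))
  arr <- array(0, c(length(ids), 6L, length(times)))
  ti <- match(df$time, times); ei <- match(df$id, ids)
  comp <- c("exx", "eyy", "ezz", "exy", "eyz", "ezx")
  for (c0 in 1:6)
    arr[cbind(ei, c0, ti)] <- df[[comp[c0]]]
  if (shear == "engineering") arr[, 4:6, ] <- arr[, 4:6, ] / 2
  strainHistory(times, arr)
}

#' @rdname readNodalHistoryCsv
#' @param strains a [StrainHistory-class].
#' @param shear shear convention written to the JSON header; the CSV always
#'   stores what the object holds (tensor shear), so only \code{"tensor"} is
#'   produced on write.
#' @export
writeStrainHistoryCsv <- function(strains, path, shear = "tensor") {
  nt <- length(strains@times)
  m <- dim(strains@tensors)[1]
  df <- data.frame(
    time = rep(strains@times, each = m),
    id = rep(seq_len(m), nt),
    exx = as.numeric(strains@tensors[, 1, ]),
    eyy = as.numeric(strains@tensors[, 2, ]),
    ezz = as.numeric(strains@tensors[, 3, ]),
    exy = as.numeric(strains@tensors[, 4, ]),
    eyz = as.numeric(strains@tensors[, 5, ]),
    ezx = as.numeric(strains@tensors[, 6, ]))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(units = list(time = "ms"), shear = "tensor"),
                       .csvSidecarPath(path), auto_unbox = TRUE)
  invisible(path)
}
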