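# Shared fixture builders; everything is generated in code.

unitCubeCorners <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
        c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
}

# Binary ellipsoid mask on an n^3 grid (1 mm spacing).
ellipsoidMask <- function(n, radii, centre = (n - 1) / 2 * c(1, 1, 1),
                          rot = diag(3)) {
  P <- morphhead:::gridWorldCoords(c(n, n, n), diag(4))
  cc <- sweep(P, 2L, centre) %*% rot     # rotate the ellipsoid frame
  q <- (cc[, 1] / radii[1])^2 + (cc[, 2] / radii[2])^2 + (cc[, 3] / radii[3])^2
  imageVolume(array(as.numeric(q <= 1), c(n, n, n)), isMask = TRUE)
}

# Affine displacement field u(x) = A x + b on an n^3 unit-spacing grid.
affineField <- function(n, A, b, convention = "resampling") {
  P <- morphhead:::gridWorldCoords(c(n, n, n), diag(4))
  U <- P %*% t(A) + matrix(b, nrow(P), 3L, byrow = TRUE)
  vectorField(array(U, c(n, n, n, 3L)), convention = convention)
}

rotZ <- function(deg) {
  th <- deg * pi / 180
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  R
}

# A random symmetric 3x3 tensor in 6-component (Exx,Eyy,Ezz,Exy,Eyz,Ezx) form.
randomSymSix <- function(scale = 0.2) {
  stats::rnorm(6L, sd = scale)
}

motionFromMap <- function(mesh, phi) {
  # two-frame nodal history: reference, then nodes mapped through phi
  n <- nrow(meshNodes(mesh))
  disp <- array(0, c(n, 3L, 2L))
  disp[, , 2L] <- phi(meshNodes(mesh)) - meshNodes(mesh)
  nodalHistory(c(0, 1), disp)
}

extdataPath <- function(file) {
  system.file("extdata", file, package = "morphhead", mustWork = TRUE)
}
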