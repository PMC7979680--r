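test_that("scaled Jacobian matches hand-computed reference shapes", {
  cube <- unitCubeCorners()
  expect_equal(scaledJacobian(cube), 1)
  # orthogonal boxes keep value 1 regardless of aspect ratio
  expect_equal(scaledJacobian(cube %*% diag(c(1, 2, 3))), 1)
  # top face sheared by 0.5 along x: corner triads give 1/sqrt(1.25)
  sheared <- cube
  sheared[5:8, 1] <- sheared[5:8, 1] + 0.5
  expect_equal(scaledJacobian(sheared), 1 / sqrt(1.25), tolerance = 1e-12)
  # reflection inverts the element
  expect_equal(scaledJacobian(cube %*% diag(c(-1, 1, 1))), -1)
  degenerate <- cube
  degenerate[2, ] <- degenerate[1, ]
  expect_error(scaledJacobian(degenerate), "zero-length edge")
})

test_that("scaled Jacobian is invariant to rigid motion and uniform scaling", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      corners <- unitCubeCorners() + matrix(stats::rnorm(24, sd = 0.1), 8L)
      sj <- scaledJacobian(corners)
      # random proper rotation from QR
      Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      s <- stats::runif(1, 0.1, 10)
      moved <- s * corners %*% t(Q) +
        matrix(stats::rnorm(3, sd = 50), 8L, 3L, byrow = TRUE)
      expect_equal(scaledJacobian(moved), sj, tolerance = 1e-9)
    }
  })
})

test_that("quality report counts fractions exactly and gates separately", {
  lat <- makeHexLattice(10, 10, 10)
  qr0 <- qualityReport(lat)
  expect_equal(qr0@minJacobian, 1)
  expect_equal(qr0@fracGe050, 1)
  expect_equal(qr0@fracGe045, 1)
  expect_true(qualityPass(qr0))

  # 10-element stack with exactly one element degraded to SJ 0.3 by shearing
  # its outer face (gamma with 1/sqrt(1 + gamma^2) = 0.3)
  stack <- makeHexLattice(1, 1, 10)
  nodes <- meshNodes(stack)
  top <- which(nodes[, 3] == 10)
  gamma <- sqrt(1 / 0.09 - 1)
  nodes[top, 1] <- nodes[top, 1] + gamma
  bad <- hexMesh(nodes, meshElements(stack), partId(stack))
  qr1 <- qualityReport(bad)
  expect_equal(qr1@fracGe050, 0.9)
  expect_equal(qr1@minJacobian, 0.3, tolerance = 1e-12)
  expect_false(qualityPass(qr1))           # fails the 95% fraction gate
  qr2 <- qualityReport(bad, floor = 0.35)
  expect_false(qualityPass(qr2))           # fails both gates; floor separate
  expect_equal(qr2@fracGe050, qr1@fracGe050)
})

test_that("morphing moves nodes by the field and preserves everything else", {
  mesh <- makeHexLattice(3, 3, 3, spacing = 2, origin = c(2, 2, 2))
  n <- 14L
  zero <- vectorField(array(0, c(n, n, n, 3L)), convention = "forward")
  m0 <- morphMesh(mesh, zero)
  expect_identical(meshNodes(m0), meshNodes(mesh))

  A <- matrix(c(0.05, 0.01, 0, 0.02, -0.03, 0.01, 0, 0.01, 0.04), 3L, 3L)
  b <- c(0.5, -0.2, 0.1)
  ua <- affineField(n, A, b, convention = "forward")
  ma <- morphMesh(mesh, ua)
  oracle <- meshNodes(mesh) + meshNodes(mesh) %*% t(A) +
    matrix(b, nrow(meshNodes(mesh)), 3L, byrow = TRUE)
  expect_equal(meshNodes(ma), oracle, tolerance = 1e-10)
  expect_identical(meshElements(ma), meshElements(mesh))
  expect_identical(partId(ma), partId(mesh))

  # pure translation leaves the quality report unchanged
  ut <- affineField(n, diag(0, 3L), c(1, 1, -0.5), convention = "forward")
  mt <- morphMesh(mesh, ut)
  expect_equal(qualityReport(mt)@perElement, qualityReport(mesh)@perElement,
               tolerance = 1e-12)

  res <- vectorField(array(0, c(n, n, n, 3L)))
  expect_error(morphMesh(mesh, res), "forward")
  outMesh <- makeHexLattice(2, 2, 2, spacing = 10)
  expect_error(morphMesh(outMesh, zero), "outside the grid")
})

test_that("morphing with a field and then its inverse restores the nodes", {
  g <- imageVolume(array(0, c(20, 20, 20)))
  w <- makeWarp("radial", 0.3, g)
  fwd <- invertField(w$field, tol = 0.005)
  mesh <- makeHexLattice(4, 4, 4, spacing = 2, origin = c(5, 5, 5))
  there <- morphMesh(mesh, fwd)
  # the original (resampling) field is the inverse map of `fwd`
  backNodes <- meshNodes(there) + sampleTrilinear(w$field, meshNodes(there))
  expect_lt(max(sqrt(rowSums((backNodes - meshNodes(mesh))^2))), 2 * 0.005)
})

test_that("element labeling uses nearest voxel with the documented tie-break", {
  lab <- array(0, c(10, 10, 10))
  lab[6, 6, 6] <- 7
  labels <- imageVolume(lab)
  one <- makeHexLattice(1, 1, 1, spacing = 1, origin = c(4.5, 4.5, 4.5))
  # centroid exactly at voxel (5,5,5) 0-based
  res <- labelElementsByImage(one, labels)
  expect_identical(as.character(res), "cerebellum")   # code 7

  # centroid exactly on a voxel boundary: lowest linear index wins
  lab2 <- array(0, c(4, 4, 4)); lab2[2, , ] <- 1; lab2[3, , ] <- 2
  onBoundary <- makeHexLattice(1, 1, 1, spacing = 1, origin = c(1, 1, 1))
  # centroid (1.5, 1.5, 1.5) sits between voxels 1 and 2 along every axis
  res2 <- labelElementsByImage(onBoundary, imageVolume(lab2))
  expect_identical(as.character(res2), "cerebralGM")  # voxel 1, code 1

  # two-region phantom split at x = 5 mm, 10 elements across
  lab3 <- array(0, c(12, 4, 4))
  lab3[1:5, , ] <- 1; lab3[6:12, , ] <- 2
  row <- makeHexLattice(10, 1, 1, spacing = 1, origin = c(0, 1, 1))
  res3 <- labelElementsByImage(row, imageVolume(lab3))
  # centroids at x = 0.5 ... 9.5; nearest voxels 0..4 -> GM (5), 5..9 -> WM (5)
  expect_identical(as.integer(table(res3)[c("cerebralGM", "cerebralWM")]),
                   c(5L, 5L))

  far <- makeHexLattice(1, 1, 1, origin = c(100, 0, 0))
  expect_warning(resF <- labelElementsByImage(far, labels), "outside")
  expect_identical(as.character(resF), "background")

  expect_error(labelElementsByImage(one, imageVolume(lab + 0.5)),
               "integer-valued")
})

test_that("VTK legacy unstructured-grid files round-trip", {
  mesh <- makeHexLattice(3, 2, 2, spacing = 1.5, origin = c(-1, 0, 2))
  pid <- rep(c(1L, 2L), length.out = 12L)
  mesh <- hexMesh(meshNodes(mesh), meshElements(mesh), pid)
  q <- qualityReport(mesh)@perElement
  f <- withr::local_tempfile(fileext = ".vtk")
  writeVtkMesh(mesh, f, quality = q)
  back <- readVtkMesh(f)
  expect_equal(meshNodes(back), meshNodes(mesh), tolerance = 1e-12)
  expect_identical(meshElements(back), meshElements(mesh))
  expect_identical(partId(back), pid)
  expect_equal(attr(back, "quality"), q, tolerance = 1e-12)
})

test_that("fiber polyline VTK output is well-formed", {
  fs <- new("FiberSet",
            lines = list(cbind(0:3, 0, 0) * 0.5, cbind(0, 0:2, 1) * 0.5),
            seedId = c(1L, 2L), meanFa = c(0.7, 0.5), step = 0.5)
  f <- withr::local_tempfile(fileext = ".vtk")
  writeVtkPolylines(fs, f)
  txt <- readLines(f)
  expect_true(any(grepl("^POINTS 7 double", txt)))
  expect_true(any(grepl("^LINES 2 9", txt)))
})
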