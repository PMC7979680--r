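test_that("head phantoms are deterministic with exact masks and labels", {
  spec <- headPhantomSpec(shape = c(32L, 32L, 32L), scale = 0.45,
                          noiseSd = 2, seed = 99L)
  p1 <- makeHeadPhantom(spec)
  p2 <- makeHeadPhantom(spec)
  expect_identical(imgData(p1$t1), imgData(p2$t1))
  expect_identical(imgData(p1$labels), imgData(p2$labels))

  # zero noise: idempotent across calls, no seed needed
  p0 <- makeHeadPhantom(headPhantomSpec(shape = c(32L, 32L, 32L), scale = 0.45))
  expect_identical(imgData(p0$t1),
                   imgData(makeHeadPhantom(headPhantomSpec(
                     shape = c(32L, 32L, 32L), scale = 0.45))$t1))

  # label volume contains exactly the declared vocabulary (full-size phantom)
  pf <- makeHeadPhantom(headPhantomSpec())
  expect_true(all(unique(imgData(pf$labels)) %in% regionCodes()))
  expect_setequal(setdiff(unique(imgData(pf$labels)), 0),
                  setdiff(regionCodes(), 0))
  # masks are binary and nested
  expect_true(all(imgData(pf$cranialMask) %in% c(0, 1)))
  expect_true(all(imgData(pf$brainMask) <= imgData(pf$cranialMask)))

  expect_error(makeHeadPhantom(headPhantomSpec(noiseSd = 1)), "seed")
})

test_that("phantom pairs bracket the published intracranial size range", {
  small <- headPhantomSpec(scale = 1)
  large <- headPhantomSpec(scale = 1.37)
  # analytic ellipsoid volumes: ratio = 1.37^3, matching the smallest-to-
  # largest adult ICV ratio of about 2.58 reported for the cohort
  ratio <- makeHeadPhantom(large)$icv / makeHeadPhantom(small)$icv
  expect_equal(ratio, 1.37^3, tolerance = 1e-12)
  expect_lt(abs(ratio - 2143.2 / 831.2), 0.02)
})

test_that("generated warps honor their closed forms and Jacobian bounds", {
  g <- imageVolume(array(0, c(24, 24, 24)))
  w0 <- makeWarp("sinusoid", 0, g)
  expect_true(all(imgData(w0$field) == 0))

  wa <- makeWarp("affine", 1, g)
  P <- morphhead:::gridWorldCoords(c(24, 24, 24), diag(4))
  expect_lt(max(abs(matrix(imgData(wa$field), ncol = 3L) - wa$evaluate(P))),
            1e-10)

  # every kind, at a representative amplitude, is numerically diffeomorphic
  for (spec in list(list("affine", 1), list("sinusoid", 1.2),
                    list("radial", 0.35))) {
    w <- makeWarp(spec[[1]], spec[[2]], g)
    expect_gt(min(jacobianDeterminant(w$field)), 0.2 - 0.05)
    expect_gte(w$jacobianLowerBound, 0.2)
  }

  # amplitudes beyond the analytic bound are refused
  expect_error(makeWarp("radial", 0.6, g), "bound")
  expect_error(makeWarp("sinusoid", 5, g), "bound")
  expect_error(makeWarp("affine", 100, g), "0.2")

  # the inverse evaluator solves (id + u)(x) = y to machine precision
  w <- makeWarp("radial", 0.3, g)
  pts <- matrix(stats::runif(30, 6, 18), 10L)
  X <- w$inverse(pts)
  expect_lt(max(abs(X + w$evaluate(X) - pts)), 1e-10)
})

test_that("hex lattices have the declared size and perfect quality", {
  one <- makeHexLattice(1, 1, 1)
  expect_identical(nrow(meshElements(one)), 1L)
  expect_identical(nrow(meshNodes(one)), 8L)
  expect_equal(meshNodes(one)[meshElements(one)[1L, ], ], unitCubeCorners())

  lat <- makeHexLattice(10, 10, 10)
  expect_identical(nrow(meshElements(lat)), 1000L)
  expect_identical(nrow(meshNodes(lat)), 1331L)
  qr <- qualityReport(lat)
  expect_true(qualityPass(qr))
  expect_equal(range(qr@perElement), c(1, 1))
})

test_that("tensor fields hit the requested FA exactly", {
  g <- imageVolume(array(0, c(10, 10, 10)))
  tf0 <- makeTensorField("uniform", 0, g)
  mesh <- makeHexLattice(2, 2, 2, origin = c(3.5, 3.5, 3.5))
  expect_true(all(fiberFa(mapDtiToElements(mesh, tf0)) == 0))

  tf <- makeTensorField("uniform", 0.7, g)
  fm <- mapDtiToElements(mesh, tf)
  expect_equal(fiberFa(fm), rep(0.7, 8), tolerance = 1e-9)
  expect_equal(fiberV1(fm), matrix(rep(c(1, 0, 0), each = 8), 8L),
               tolerance = 1e-12)
  # unit trace by construction
  six <- imgData(tf)[1, 1, 1, ]
  expect_equal(six[1] + six[4] + six[6], 1, tolerance = 1e-12)
  expect_error(makeTensorField("uniform", 1, g), "faTarget")
})

test_that("impact histories recover their analytic strain ground truth", {
  mesh <- makeHexLattice(3, 3, 3)
  # rigid rotation mode: strain is zero at every instant
  rot <- makeImpactHistory(mesh, "rotation", peakTime = 36, amplitude = 0.4)
  shR <- elementStrainHistory(mesh, rot$motion)
  expect_lt(max(abs(shR@tensors)), 1e-10)
  expect_equal(rot$analytic$mps, 0, tolerance = 1e-14)

  # stretch 1.2 peaking at 36 ms: MPS 0.22 at 36 ms, recovered exactly
  st <- makeImpactHistory(mesh, "stretch", peakTime = 36, amplitude = 1.2)
  shS <- elementStrainHistory(mesh, st$motion)
  pk <- suppressWarnings(regionalPeaks(shS, rep(2L, 27)))
  expect_equal(pk$peak, 0.22, tolerance = 1e-12)
  expect_equal(pk$time, 36)
  expect_equal(st$analytic$mps, 0.22, tolerance = 1e-14)

  # fiber along the stretch axis: MAS = MPS; perpendicular: closed form
  expect_equal(st$analytic$mas(c(1, 0, 0)), st$analytic$mps,
               tolerance = 1e-14)
  expect_equal(st$analytic$mas(c(0, 1, 0)), 0, tolerance = 1e-14)
  vd <- c(1, 1, 0) / sqrt(2)
  Fp <- diag(c(1.2, 1, 1))
  expect_equal(st$analytic$mas(vd),
               as.numeric(vd %*% ((t(Fp) %*% Fp - diag(3)) / 2) %*% vd),
               tolerance = 1e-14)

  # rotation composed with stretch changes nothing (objectivity)
  mx <- makeImpactHistory(mesh, "mix", peakTime = 36, amplitude = 1.2)
  shM <- elementStrainHistory(mesh, mx$motion)
  expect_equal(max(morphhead:::.principalFromSix(
    matrix(shM@tensors[, , which(mx$motion@times == 36)], ncol = 6))),
    0.22, tolerance = 1e-10)

  expect_error(makeImpactHistory(mesh, "stretch", peakTime = 36,
                                 amplitude = 1.2, noiseSd = 0.1), "seed")
  expect_error(makeImpactHistory(mesh, "stretch", peakTime = 35,
                                 amplitude = 1.2, dt = 4), "peak")
})
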