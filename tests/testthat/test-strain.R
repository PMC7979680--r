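test_that("Green-Lagrange strain matches closed forms for canonical motions", {
  m <- makeHexLattice(1, 1, 1)
  # rigid rotation: objectivity gives exactly zero strain
  sh <- elementStrainHistory(m, motionFromMap(m, function(x) x %*% t(rotZ(30))))
  expect_lt(max(abs(sh@tensors[, , 2])), 1e-12)

  # uniaxial stretch 1.2 along x: Exx = (1.2^2 - 1)/2 = 0.22
  sh2 <- elementStrainHistory(
    m, motionFromMap(m, function(x) x %*% diag(c(1.2, 1, 1))))
  expect_equal(as.numeric(sh2@tensors[, , 2]), c(0.22, 0, 0, 0, 0, 0),
               tolerance = 1e-14)

  # simple shear gamma = 0.5: Exy = 0.25, Eyy = 0.125, Exx = 0
  shr <- function(x) cbind(x[, 1] + 0.5 * x[, 2], x[, 2], x[, 3])
  sh3 <- elementStrainHistory(m, motionFromMap(m, shr))
  expect_equal(as.numeric(sh3@tensors[, , 2]),
               c(0, 0.125, 0, 0.25, 0, 0), tolerance = 1e-14)
})

test_that("strain is exact on random affine motions against the F-based oracle", {
  mesh <- makeHexLattice(3, 2, 2, spacing = 1.7, origin = c(1, 2, 3))
  withr::with_seed(21, {
    for (rep in 1:8) {
      A <- diag(3) + matrix(stats::rnorm(9, sd = 0.15), 3L)
      b <- stats::rnorm(3)
      sh <- elementStrainHistory(
        mesh, motionFromMap(mesh, function(x) {
          x %*% t(A) + matrix(b, nrow(x), 3L, byrow = TRUE)
        }))
      Eo <- (t(A) %*% A - diag(3)) / 2
      oracle <- c(Eo[1, 1], Eo[2, 2], Eo[3, 3], Eo[1, 2], Eo[2, 3], Eo[1, 3])
      for (e in seq_len(nrow(meshElements(mesh))))
        expect_equal(as.numeric(sh@tensors[e, , 2]), oracle,
                     tolerance = 1e-10)
    }
  })
})

test_that("principal strain matches 2x2 closed form and is rotation invariant", {
  expect_equal(principalStrain(diag(c(0.22, 0, 0))), 0.22)
  shearE <- c(0, 0.125, 0, 0.25, 0, 0)
  expect_equal(principalStrain(shearE),
               (0.125 + sqrt(0.125^2 + 4 * 0.0625)) / 2, tolerance = 1e-12)
  withr::with_seed(9, {
    for (rep in 1:10) {
      E <- morphhead:::.tensorFromSixE(randomSymSix())
      Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
      expect_equal(principalStrain(Q %*% E %*% t(Q)), principalStrain(E),
                   tolerance = 1e-10)
      # the vectorized analytic eigenvalue agrees with eigen()
      six <- c(E[1, 1], E[2, 2], E[3, 3], E[1, 2], E[2, 3], E[1, 3])
      expect_equal(morphhead:::.principalFromSix(matrix(six, 1L)),
                   eigen(E, symmetric = TRUE, only.values = TRUE)$values[1],
                   tolerance = 1e-10)
    }
  })
})

test_that("axonal strain is the Rayleigh quotient with its extremal bounds", {
  E <- diag(c(0.1, -0.05, 0))
  expect_equal(axonalStrain(E, c(1, 0, 0)), 0.1)
  expect_equal(axonalStrain(E, c(1, 1, 0) / sqrt(2)), 0.025, tolerance = 1e-14)
  # an eigenvector attains its eigenvalue exactly
  withr::with_seed(13, {
    D <- morphhead:::.tensorFromSixE(randomSymSix())
    ev <- eigen(D, symmetric = TRUE)
    expect_equal(axonalStrain(D, ev$vectors[, 1]), ev$values[1],
                 tolerance = 1e-12)
  })
  expect_error(axonalStrain(E, c(1, 1, 0)), "unit vector")
})

test_that("regional peaks locate value, element and time; percentile is nearest-rank", {
  # single element, Exx ramp peaking 0.3 at t = 36
  times <- seq(0, 72, by = 12)
  ramp <- 0.3 * sin(pi * times / 72)^2
  tens <- array(0, c(1, 6, length(times)))
  tens[1, 1, ] <- ramp
  pk <- suppressWarnings(regionalPeaks(strainHistory(times, tens), labels = 2L))
  mpsRow <- pk[pk$metric == "MPS", ]
  expect_equal(mpsRow$peak, 0.3)
  expect_equal(mpsRow$time, 36)
  expect_identical(mpsRow$element, 1L)

  # two elements peaking 0.3 @ 40 and 0.5 @ 56: region peak follows the larger
  t2 <- seq(0, 80, by = 8)
  tens2 <- array(0, c(2, 6, length(t2)))
  tens2[1, 1, ] <- 0.3 * exp(-((t2 - 40) / 15)^2)
  tens2[2, 1, ] <- 0.5 * exp(-((t2 - 56) / 15)^2)
  tens2[, , 1] <- 0
  pk2 <- suppressWarnings(regionalPeaks(strainHistory(t2, tens2), labels = c(1L, 1L)))
  expect_equal(pk2$peak, 0.5)
  expect_identical(pk2$element, 2L)
  expect_equal(pk2$time, 56)

  # 100 elements with known static principal strains: 95th percentile is the
  # nearest-rank order statistic
  withr::with_seed(31, {
    vals <- stats::runif(100, 0, 0.6)
  })
  tens3 <- array(0, c(100, 6, 2))
  tens3[, 1, 2] <- vals
  pk3 <- suppressWarnings(regionalPeaks(strainHistory(c(0, 1), tens3),
                       labels = rep(1L, 100), percentile = 95))
  expect_equal(pk3$peak, sort(vals)[ceiling(0.95 * 100)])
  expect_identical(pk3$element, which(vals == sort(vals)[95]))
})

test_that("MAS is evaluated only in anisotropic regions and never exceeds MPS", {
  withr::with_seed(17, {
    m <- 60L
    tens <- array(stats::rnorm(m * 6 * 4, sd = 0.1), c(m, 6, 4))
    tens[, , 1] <- 0
    v <- matrix(stats::rnorm(m * 3), m)
    v <- v / sqrt(rowSums(v^2))
    fib <- new("ElementFiberMap", fa = rep(0.5, m), v1 = v,
               outsideCount = 0L)
    labs <- rep(c(1L, 2L, 3L, 5L), length.out = m)  # GM, WM, CC, hippocampus
    expect_warning(pk <- regionalPeaks(strainHistory(0:3, tens), labs, fib),
                   "omitted")
    expect_setequal(pk$region[pk$metric == "MAS"], c("cerebralWM", "CC"))
    expect_true(all(c("cerebralGM", "hippocampus") %in%
                    pk$region[pk$metric == "MPS"]))
    # projection bound, elementwise over the whole history
    for (ti in 2:4) {
      mps <- morphhead:::.principalFromSix(matrix(tens[, , ti], ncol = 6))
      mas <- morphhead:::.axonalFromSix(matrix(tens[, , ti], ncol = 6), v)
      expect_true(all(mas <= mps + 1e-12))
    }
  })
})

test_that("peak tables are invariant to element permutation", {
  withr::with_seed(23, {
    m <- 40L
    tens <- array(stats::rnorm(m * 6 * 3, sd = 0.1), c(m, 6, 3))
    tens[, , 1] <- 0
    labs <- rep(c(2L, 3L), length.out = m)
    v <- matrix(stats::rnorm(m * 3), m); v <- v / sqrt(rowSums(v^2))
    fib <- new("ElementFiberMap", fa = rep(0.4, m), v1 = v, outsideCount = 0L)
    pk <- suppressWarnings(regionalPeaks(strainHistory(0:2, tens), labs, fib))
    perm <- sample(m)
    fibP <- new("ElementFiberMap", fa = rep(0.4, m), v1 = v[perm, ],
                outsideCount = 0L)
    pkP <- suppressWarnings(regionalPeaks(
      strainHistory(0:2, tens[perm, , ]), labs[perm], fibP))
    ord <- order(pk$region, pk$metric); ordP <- order(pkP$region, pkP$metric)
    expect_equal(pk$peak[ord], pkP$peak[ordP], tolerance = 1e-12)
    expect_equal(pk$time[ord], pkP$time[ordP])
    # element ids map through the permutation
    expect_identical(perm[pkP$element[ordP]], pk$element[ord])
  })
})

test_that("history CSV round trips, including engineering shear conversion", {
  mesh <- makeHexLattice(2, 1, 1)
  mot <- motionFromMap(mesh, function(x) x %*% diag(c(1.1, 1, 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeNodalHistoryCsv(mot, f)
  back <- readNodalHistoryCsv(f)
  expect_equal(back@displacements, mot@displacements, tolerance = 1e-12)

  sh <- elementStrainHistory(mesh, mot)
  fs <- withr::local_tempfile(fileext = ".csv")
  writeStrainHistoryCsv(sh, fs)
  expect_equal(readStrainHistoryCsv(fs)@tensors, sh@tensors, tolerance = 1e-12)

  # engineering-shear input is halved on import
  df <- utils::read.csv(fs)
  df[, c("exy", "eyz", "ezx")] <- df[, c("exy", "eyz", "ezx")] * 2
  fe <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, fe, row.names = FALSE)
  jsonlite::write_json(list(shear = "engineering"),
                       sub("\\.csv$", ".json", fe), auto_unbox = TRUE)
  expect_equal(readStrainHistoryCsv(fe)@tensors, sh@tensors, tolerance = 1e-12)
})
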