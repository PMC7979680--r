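test_that("trilinear sampling reproduces constants, stored values and linear fields", {
  n <- 10L
  u <- vectorField(array(rep(c(1, 2, 3), each = n^3), c(n, n, n, 3L)))
  pts <- matrix(runif(30, 1, 8), 10L)
  expect_equal(sampleTrilinear(u, pts),
               matrix(rep(c(1, 2, 3), each = 10L), 10L), tolerance = 1e-14)

  A <- matrix(c(0.1, 0.02, 0, 0.01, -0.05, 0.03, 0, 0.02, 0.08), 3L, 3L)
  b <- c(0.5, -1, 2)
  ua <- affineField(n, A, b)
  withr::with_seed(7, {
    pts <- matrix(runif(60, 0.5, 8.5), 20L)
  })
  expect_equal(sampleTrilinear(ua, pts),
               pts %*% t(A) + matrix(b, 20L, 3L, byrow = TRUE),
               tolerance = 1e-12)

  # u(x) = 0.1 x, arbitrary interior points
  us <- affineField(n, diag(0.1, 3L), c(0, 0, 0))
  expect_equal(sampleTrilinear(us, pts), 0.1 * pts, tolerance = 1e-12)

  # exact voxel centre returns the stored value
  arr <- array(stats::rnorm(n^3), c(n, n, n))
  img <- imageVolume(arr)
  expect_identical(sampleTrilinear(img, matrix(c(3, 5, 7), 1L)), arr[4, 6, 8])
})

test_that("out-of-domain sampling errors beyond tolerance and clamps within", {
  img <- imageVolume(array(1:27, c(3, 3, 3)) * 1.0)
  expect_error(sampleTrilinear(img, matrix(c(5, 1, 1), 1L)), "outside the grid")
  # within 0.5 voxel: clamped, no error
  expect_silent(v <- sampleTrilinear(img, matrix(c(2.4, 1, 1), 1L)))
  expect_equal(v, sampleTrilinear(img, matrix(c(2, 1, 1), 1L)))
  expect_silent(sampleTrilinear(img, matrix(c(5, 1, 1), 1L), outside = "clamp"))
})

test_that("warpImage follows resampling semantics and preserves label sets", {
  n <- 9L
  arr <- array(0, c(n, n, n)); arr[5, 5, 5] <- 1
  img <- imageVolume(arr)
  zero <- vectorField(array(0, c(n, n, n, 3L)))
  expect_identical(imgData(warpImage(img, zero)), arr)

  # constant +a displaces an impulse by -a on the output grid
  a <- c(2, 0, 0)
  uc <- vectorField(array(rep(a, each = n^3), c(n, n, n, 3L)))
  w <- warpImage(img, uc)
  expect_identical(which(imgData(w) == 1, arr.ind = TRUE),
                   matrix(c(3L, 5L, 5L), 1L,
                          dimnames = list(NULL, c("dim1", "dim2", "dim3"))))

  # nearest interpolation keeps a mask binary
  mask <- imageVolume(array(as.numeric(arr > 0), c(n, n, n)), isMask = TRUE)
  us <- vectorField(array(rep(c(0.4, 0.3, -0.2), each = n^3), c(n, n, n, 3L)))
  wm <- warpImage(mask, us, "nearest")
  expect_true(all(imgData(wm) %in% c(0, 1)))
  expect_true(isMask(wm))

  fwd <- vectorField(array(0, c(n, n, n, 3L)), convention = "forward")
  expect_error(warpImage(img, fwd), "resampling")
})

test_that("field composition matches matrix algebra and is associative on affines", {
  n <- 12L
  A1 <- matrix(c(0.05, 0.01, 0, 0.02, -0.03, 0.01, 0, 0.01, 0.04), 3L, 3L)
  b1 <- c(1, 2, 3)
  A2 <- matrix(c(-0.03, 0, 0.01, 0, 0.02, 0, 0.01, 0, 0.03), 3L, 3L)
  b2 <- c(-0.5, 1, 0.2)
  u1 <- affineField(n, A1, b1)
  u2 <- affineField(n, A2, b2)

  expect_equal(imgData(composeFields(u1, affineField(n, diag(0, 3L), c(0, 0, 0)),
                                     outside = "clamp")),
               imgData(u1), tolerance = 1e-14)

  ut <- composeFields(u1, u2, outside = "clamp")
  P <- morphhead:::gridWorldCoords(c(n, n, n), diag(4))
  U1 <- P %*% t(A1) + matrix(b1, nrow(P), 3L, byrow = TRUE)
  oracle <- U1 + (P + U1) %*% t(A2) + matrix(b2, nrow(P), 3L, byrow = TRUE)
  Q <- P + U1
  interior <- apply(Q >= 0 & Q <= n - 1, 1L, all)
  expect_true(mean(interior) > 0.3)
  expect_lt(max(abs((matrix(imgData(ut), ncol = 3L) - oracle)[interior, ])),
            1e-10)

  # associativity on the subgrid where all compositions stay interior
  A3 <- diag(c(0.02, -0.01, 0.03)); b3 <- c(0.3, -0.2, 0.1)
  u3 <- affineField(n, A3, b3)
  lhs <- composeFields(composeFields(u1, u2, outside = "clamp"), u3,
                       outside = "clamp")
  rhs <- composeFields(u1, composeFields(u2, u3, outside = "clamp"),
                       outside = "clamp")
  Q2 <- P + matrix(imgData(lhs), ncol = 3L)
  interior2 <- interior & apply(Q2 >= 1 & Q2 <= n - 2, 1L, all)
  expect_lt(max(abs((matrix(imgData(lhs), ncol = 3L) -
                     matrix(imgData(rhs), ncol = 3L))[interior2, ])), 1e-9)

  # constants compose to their sum under both modes
  ca <- affineField(n, diag(0, 3L), c(1, -2, 0.5))
  cb <- affineField(n, diag(0, 3L), c(0.2, 0.3, -0.1))
  expect_equal(imgData(composeFields(ca, cb, outside = "clamp")),
               imgData(composeFields(ca, cb, mode = "sum")), tolerance = 1e-14)

  conv <- vectorField(imgData(u2), convention = "forward")
  expect_error(composeFields(u1, conv), "different conventions")
})

test_that("field inversion satisfies the inverse identity and flips convention", {
  n <- 12L
  # constant field inverts to its negation
  uc <- affineField(n, diag(0, 3L), c(1.5, -0.7, 0.3))
  vc <- invertField(uc)
  expect_equal(matrix(imgData(vc), ncol = 3L),
               matrix(rep(-c(1.5, -0.7, 0.3), each = n^3), ncol = 3L),
               tolerance = 1e-10)
  expect_identical(fieldConvention(vc), "forward")

  # affine field matches the closed-form inverse on interior voxels
  A <- matrix(c(0.05, 0.01, 0, 0.02, -0.03, 0.01, 0, 0.01, 0.04), 3L, 3L)
  b <- c(1, 2, 3)
  u <- affineField(n, A, b)
  tol <- 0.002
  v <- invertField(u, tol = tol)
  P <- morphhead:::gridWorldCoords(c(n, n, n), diag(4))
  closed <- sweep(P, 2L, b) %*% t(solve(diag(3) + A)) - P
  interior <- apply(P + closed >= 0 & P + closed <= n - 1, 1L, all)
  expect_lt(max(abs((matrix(imgData(v), ncol = 3L) - closed)[interior, ])),
            3 * tol)

  # compose(u, invert(u)) is the identity within tolerance (interior);
  # conventions intentionally differ after inversion, so compose refuses
  expect_error(composeFields(u, v), "different conventions")
  Uv <- sampleTrilinear(u, P[interior, ] + matrix(imgData(v),
                                                  ncol = 3L)[interior, ],
                        outside = "clamp")
  expect_lt(max(abs(Uv + matrix(imgData(v), ncol = 3L)[interior, ])), 2 * tol)
})

test_that("inversion of generated diffeomorphic warps is inverse-consistent", {
  g <- imageVolume(array(0, c(24, 24, 24)))
  for (kind in c("sinusoid", "radial")) {
    amp <- if (kind == "sinusoid") 1.2 else 0.3
    w <- makeWarp(kind, amp, g)
    expect_gt(min(jacobianDeterminant(w$field)), 0)
    v <- invertField(w$field, tol = 0.005)
    P <- morphhead:::gridWorldCoords(c(24, 24, 24), diag(4))
    V <- matrix(imgData(v), ncol = 3L)
    interior <- apply(P + V >= 1 & P + V <= 22, 1L, all)
    res <- sampleTrilinear(w$field, P[interior, ] + V[interior, ],
                           outside = "clamp") + V[interior, ]
    expect_lt(max(abs(res)), 0.01)
  }
})

test_that("non-diffeomorphic fields trigger a best-effort warning", {
  n <- 10L
  u <- affineField(n, diag(-1.5, 3L), c(0, 0, 0))  # folds space
  expect_warning(try(invertField(u, maxIter = 5L), silent = TRUE),
                 "not diffeomorphic")
})

test_that("NIfTI round trips preserve data, affine, and convention sidecar", {
  arr <- array(stats::rnorm(6 * 5 * 4), c(6, 5, 4))
  A <- affineFromSpacing(c(1, 1.25, 2), c(-10, 4, 3))
  img <- imageVolume(arr, affine = A)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiVolume(img, f)
  img2 <- readNiftiVolume(f)
  expect_equal(imgData(img2), arr, tolerance = 1e-6)
  expect_equal(imgAffine(img2), A, tolerance = 1e-5)

  u <- vectorField(array(stats::rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3L)),
                   affine = A, convention = "forward")
  fu <- withr::local_tempfile(fileext = ".nii.gz")
  writeVectorFieldNifti(u, fu)
  u2 <- readVectorFieldNifti(fu)
  expect_equal(imgData(u2), imgData(u), tolerance = 1e-6)
  expect_identical(fieldConvention(u2), "forward")

  tv <- tensorVolume(array(stats::rnorm(4^3 * 6), c(4, 4, 4, 6L)))
  ft <- withr::local_tempfile(fileext = ".nii.gz")
  writeTensorVolumeNifti(tv, ft)
  expect_equal(imgData(readTensorVolumeNifti(ft)), imgData(tv),
               tolerance = 1e-6)
})

test_that("rigid transforms compose with their inverse to the identity", {
  R <- rotZ(37) %*% rotZ(0)  # proper rotation
  tr <- rigidTransform(R, c(4, -2, 1))
  id <- rigidCompose(tr, rigidInverse(tr))
  expect_lt(max(abs(id@rotation - diag(3))), 1e-10)
  expect_lt(max(abs(id@translation)), 1e-10)
})

test_that("masks reject non-binary content and affines must be invertible", {
  expect_error(imageVolume(array(0.5, c(2, 2, 2)), isMask = TRUE), "mask")
  expect_error(imageVolume(array(0, c(2, 2, 2)),
                           affine = matrix(0, 4, 4)), "invertible")
})
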