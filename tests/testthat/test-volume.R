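# Volume container, NIfTI round trips, resampling, smoothing, rigid init.

test_that("NIfTI write/read round trip preserves data and geometry", {
  set.seed(1)
  v <- volume(array(rnorm(16^3), c(16, 16, 16)),
              spacing = c(0.47, 0.47, 0.7), origin = c(-10.5, 3, 7.25))
  f <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
  expect_equal(v2$direction, v$direction, tolerance = 1e-6)

  # masks keep {0,1} on disk
  m <- binary_mask(array(rbinom(8^3, 1, 0.3), c(8, 8, 8)))
  fm <- file.path(tempdir(), "mask.nii.gz")
  write_volume(m, fm)
  expect_true(all(read_volume(fm)$data %in% c(0, 1)))
})

test_that("volume validation rejects bad inputs", {
  expect_error(volume(matrix(1:4, 2)), "3D")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)), "positive")
  expect_error(volume(array(1, c(2, 2, 2)),
                      direction = matrix(2 * diag(3), 3)), "orthonormal")
  expect_error(volume(array(NA_real_, c(2, 2, 2))), "NA")
  expect_error(binary_mask(array(0.5, c(2, 2, 2))), "0 or 1")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  expect_error(write_volume(volume(array(0, c(2, 2, 2))),
                            "/nonexistent-dir/x.nii"), "directory")
})

test_that("read_volume rejects 2D images", {
  f <- file.path(tempdir(), "flat.nii.gz")
  img <- RNifti::asNifti(matrix(rnorm(64), 8))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3D")
})

test_that("resample_isotropic preserves extent, identity, and constants", {
  set.seed(2)
  v <- volume(array(rnorm(20 * 16 * 12), c(20, 16, 12)),
              spacing = c(1, 1.5, 2.5))
  iso <- resample_isotropic(v, 1)
  expect_equal(iso$spacing, c(1, 1, 1))
  extent_in <- dim(v$data) * v$spacing
  extent_out <- dim(iso$data) * iso$spacing
  expect_true(all(abs(extent_in - extent_out) <= 1 + 1e-9))
  expect_true(min(iso$data) >= min(v$data) - 1e-9)
  expect_true(max(iso$data) <= max(v$data) + 1e-9)

  # identity resample
  same <- resample_isotropic(volume(array(rnorm(8^3), c(8, 8, 8))), 1)
  expect_equal(same$data, array(same$data, c(8, 8, 8)), tolerance = 1e-6)

  # constants stay constant
  cv <- volume(array(7, c(9, 7, 5)), spacing = c(1, 2, 3))
  expect_equal(range(resample_isotropic(cv, 1.3)$data), c(7, 7),
               tolerance = 1e-9)

  expect_error(resample_isotropic(v, 0), "positive")
})

test_that("resampling a world-coordinate ramp is analytically exact", {
  d <- c(16L, 16L, 16L)
  g <- volume(array(0, d), spacing = c(2, 2, 2))
  X <- neotemplate:::voxel_centers_world(g)
  g$data <- array(X[, 1], d)   # f(x) = x (world mm along first axis)
  fine <- resample_isotropic(g, 1)
  Xf <- neotemplate:::voxel_centers_world(fine)
  inside <- Xf[, 1] >= 0 & Xf[, 1] <= (d[1] - 1) * 2
  expect_lt(max(abs(fine$data[inside] - Xf[inside, 1])), 1e-3)
})

test_that("nearest-neighbour resampling keeps masks binary", {
  set.seed(3)
  m <- binary_mask(array(rbinom(10^3, 1, 0.4), c(10, 10, 10)),
                   spacing = c(1, 2, 1.3))
  r <- resample_isotropic(m, 0.9)
  expect_s3_class(r, "nt_mask")
  expect_true(all(r$data %in% c(0, 1)))
})

test_that("gaussian smoothing: identity at zero width, mass conservation,
           impulse response, scaling equivariance", {
  set.seed(4)
  v <- volume(array(rnorm(16^3), c(16, 16, 16)))
  expect_identical(gaussian_smooth(v, 0)$data, v$data)
  expect_error(gaussian_smooth(v, -1), "non-negative")

  # interior impulse -> analytic discrete Gaussian
  d <- c(21L, 21L, 21L)
  imp <- volume(array(0, d)); imp$data[11, 11, 11] <- 1
  sm <- gaussian_smooth(imp, 2)           # spacing 1 mm
  sigma <- fwhm_to_sigma(2)
  r <- 4
  off <- -r:r
  k1 <- exp(-0.5 * off^2 / sigma^2)
  # kernel radius used internally is ceil(4*sigma)
  rr <- ceiling(4 * sigma)
  k1 <- exp(-0.5 * (-rr:rr)^2 / sigma^2); k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  got <- sm$data[11 + (-rr:rr), 11 + (-rr:rr), 11 + (-rr:rr)]
  expect_lt(max(abs(got - expected)), 1e-4)

  # total mass of an interior blob is conserved
  blob <- volume(array(0, d)); blob$data[9:13, 9:13, 9:13] <- 2
  expect_lt(abs(sum(gaussian_smooth(blob, 2)$data) - sum(blob$data)) /
              sum(blob$data), 1e-6)

  # smoothing commutes with intensity scaling
  a <- 3.7
  s1 <- gaussian_smooth(volume(a * v$data), 3)$data
  s2 <- a * gaussian_smooth(v, 3)$data
  expect_lt(max(abs(s1 - s2)), 1e-10)
})

test_that("rigid initializer recovers translations and rotations", {
  # the initializer runs on preprocessed (cleaned) CT in the pipeline, so the
  # contract is checked on a nuisance-free phantom
  ph <- generate_head_phantom(mid_spec(nuisance_blobs = 0L,
                                       rim_value = -1000))
  ct <- ph$ct
  expect_error(rigid_initialize(volume(array(1, c(4, 4, 4))), ct),
               "degenerate|constant")

  t0 <- rigid_initialize(ct, ct)
  expect_lt(max(abs(t0$matrix - diag(3))), 1e-3)
  expect_lt(max(abs(t0$translation)), 1e-3)

  # pure translation by 10 mm; the pull-back convention recovers the
  # negated shift
  tr <- affine_transform(diag(3), c(10, 0, 0))
  mv <- apply_transform(ct, tr, fill = -1000)
  est <- rigid_initialize(mv, ct)
  expect_lt(max(abs(est$translation - c(-10, 0, 0))), min(ct$spacing))

  # 10 degree axial rotation about the head center
  ctr <- (dim(ct$data) - 1) / 2 * ct$spacing
  R <- neotemplate:::rot3(3, 10 * pi / 180)
  rot <- affine_transform(R, as.numeric(ctr - R %*% ctr))
  mvr <- apply_transform(ct, rot, fill = -1000)
  estr <- rigid_initialize(mvr, ct)
  ang <- acos(min(1, (sum(diag(estr$matrix)) - 1) / 2)) * 180 / pi
  expect_lt(abs(ang - 10), 2)
  # rigid: orthonormal rotation part
  expect_lt(max(abs(crossprod(estr$matrix) - diag(3))), 1e-6)
})
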