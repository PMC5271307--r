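# Transform algebra: composition, inversion, application, serialization.

test_that("affine composition and inversion are exact", {
  set.seed(30)
  A <- affine_transform(neotemplate:::rot3(3, 0.3) %*% diag(c(1.1, 0.9, 1)),
                        c(4, -2, 1))
  Ai <- invert_affine(A)
  comp <- neotemplate:::affine_after(A, Ai)
  expect_lt(max(abs(comp$matrix - diag(3))), 1e-6)
  expect_lt(max(abs(comp$translation)), 1e-6)
  expect_error(affine_transform(diag(c(-1, 1, 1))), "determinant")
  # empty composition is the identity
  id <- compose_transforms(list())
  X <- matrix(rnorm(30), 10)
  expect_equal(map_points(id, X), X)
  expect_equal(map_points(compose_transforms(list(identity_transform())), X),
               X)
})

test_that("apply_transform: identity, exact integer shifts, and
           composition-vs-sequential equivalence", {
  ph <- generate_head_phantom(tiny_spec())
  ct <- ph$ct
  # identity
  out <- apply_transform(ct, identity_transform(), interp = "linear",
                         fill = -1000)
  expect_lt(max(abs(out$data - ct$data)), 1e-6)
  out_n <- apply_transform(ct, identity_transform(), interp = "nearest",
                           fill = -1000)
  expect_identical(out_n$data, ct$data)

  # integer-voxel translation with nearest interpolation: exact shift
  sh <- affine_transform(diag(3), c(ct$spacing[1] * 2, 0, 0))
  shifted <- apply_transform(ct, sh, interp = "nearest", fill = -1000)
  d <- dim(ct$data)
  expect_identical(shifted$data[1:(d[1] - 2), , ], ct$data[3:d[1], , ])
  expect_true(all(shifted$data[(d[1] - 1):d[1], , ] == -1000))

  # apply(t2, apply(t1, V)) == apply(compose(t1, t2), V) within interpolation
  # (noise-free phantom: the comparison measures geometry, and double
  # interpolation of voxel noise would dominate otherwise)
  ph0 <- generate_head_phantom(mid_spec(noise_sd = 0, mr_noise_sd = 0,
                                        nuisance_blobs = 0L))
  cq <- ph0$ct
  t1 <- affine_transform(diag(3), c(3, -2, 1))
  fld <- array(0, c(dim(cq$data), 3)); fld[, , , 2] <- 2.5
  t2 <- diffeo_transform(fld, -fld, cq)
  seq2 <- apply_transform(apply_transform(cq, t1, fill = -1000), t2,
                          fill = -1000, ref = cq)
  both <- apply_transform(cq, compose_transforms(list(t1, t2)),
                          fill = -1000, ref = cq)
  rngv <- diff(range(cq$data))
  expect_lt(mean(abs(seq2$data - both$data)) / rngv, 0.01)
})

test_that("composing a diffeo with its inverse is near the identity", {
  ph <- generate_head_phantom(tiny_spec())
  geom <- ph$ct
  d <- dim(geom$data)
  set.seed(31)
  fld <- array(rnorm(prod(d) * 3), c(d, 3))
  fld <- neotemplate:::smooth_field(fld, c(3, 3, 3), zeropad = TRUE)
  fld <- fld * (3 / max(abs(fld)))
  dt <- diffeo_transform(fld, neotemplate:::invert_field(fld, geom), geom)
  X <- neotemplate:::voxel_centers_world(geom)
  sub <- X[seq(1, nrow(X), 11), ]
  back <- map_points(dt, map_points(dt, sub), inverse = TRUE)
  res_vox <- sqrt(rowSums((back - sub)^2)) / min(geom$spacing)
  expect_lt(mean(res_vox), 0.1)
  expect_lt(max(res_vox), 0.5)
})

test_that("jacobian determinant matches closed forms", {
  geom <- volume(array(0, c(12, 12, 12)), spacing = c(2, 2, 2))
  d <- c(12, 12, 12)
  # zero field -> unit determinant
  z <- array(0, c(d, 3))
  expect_equal(range(jacobian_determinant(z, geom)), c(1, 1))
  # uniform linear expansion u = a*x -> det = (1+a)^3
  X <- neotemplate:::voxel_centers_world(geom)
  a <- 0.1
  fld <- array(a * X, c(d, 3))
  jd <- jacobian_determinant(fld, geom)
  interior <- jd[2:11, 2:11, 2:11]
  expect_equal(range(interior), rep((1 + a)^3, 2), tolerance = 1e-9)
})

test_that("transforms serialize and deserialize faithfully", {
  dir <- file.path(tempdir(), "tr")
  dir.create(dir, showWarnings = FALSE)
  A <- affine_transform(neotemplate:::rot3(1, 0.2), c(1.5, -3, 2))
  f <- write_transform(A, file.path(dir, "aff"))
  A2 <- read_transform(f)
  expect_equal(A2$matrix, A$matrix, tolerance = 1e-12)
  expect_equal(A2$translation, A$translation, tolerance = 1e-12)

  geom <- volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
  set.seed(32)
  fld <- neotemplate:::smooth_field(array(rnorm(8^3 * 3), c(8, 8, 8, 3)),
                                    c(2, 2, 2))
  dt <- diffeo_transform(fld, -fld, geom)
  fd <- write_transform(dt, file.path(dir, "dif"))
  dt2 <- read_transform(fd)
  expect_equal(dt2$forward, dt$forward, tolerance = 1e-12)
  expect_equal(dt2$inverse, dt$inverse, tolerance = 1e-12)

  comp <- compose_transforms(list(A, dt))
  fc <- write_transform(comp, file.path(dir, "comp"))
  comp2 <- read_transform(fc)
  X <- matrix(runif(30, 2, 12), 10)
  expect_equal(map_points(comp2, X), map_points(comp, X), tolerance = 1e-9)
})
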