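# Affine and symmetric diffeomorphic registration (fast mid-size checks; the
# full-scale recovery battery lives in the acceptance suite).

test_that("affine registration of an image to itself is the identity", {
  ph <- generate_head_phantom(mid_spec())
  est <- affine_register(ph$ct, ph$ct, metric = "CC", params = fast_affine())
  expect_lt(max(abs(est$matrix - diag(3))), 1e-3)
  expect_lt(max(abs(est$translation)), 1e-3)
  expect_gte(attr(est, "metric"), attr(est, "metric_init"))
})

test_that("affine registration recovers a known shift under MI and never
           scores below its initialization", {
  ph <- generate_head_phantom(mid_spec())
  ct <- ph$ct
  shift <- affine_transform(diag(3), c(7.5, 0, 0))
  mv <- apply_transform(ct, shift, fill = -1000)
  est <- affine_register(mv, ct, metric = "MI", params = fast_affine())
  # pull-back convention: the recovered map is the inverse image motion
  expect_lt(max(abs(est$translation - c(-7.5, 0, 0))) / min(ct$spacing), 0.5)
  expect_gte(attr(est, "metric"), attr(est, "metric_init"))
  # no-overlap failure
  far <- volume(ct$data, spacing = ct$spacing, origin = c(1e4, 1e4, 1e4))
  expect_error(suppressWarnings(
    affine_register(far, ct, metric = "MI",
                    init = identity_transform(), params = fast_affine())),
    "overlap|failure")
})

test_that("diffeomorphic registration: identity input gives a null field;
           metric trace is non-decreasing up to backtracking", {
  ph <- generate_head_phantom(mid_spec())
  est <- syn_register(ph$ct, ph$ct, metric = "CC", params = fast_syn())
  expect_lt(max(abs(est$forward)) / min(ph$ct$spacing), 0.1)
  tr <- attr(est, "trace")
  expect_gte(tr$metric[nrow(tr)], tr$metric[1])
})

test_that("diffeomorphic registration is symmetric and inverse-consistent
           with positive Jacobians", {
  ph <- generate_head_phantom(mid_spec(nuisance_blobs = 0L,
                                       rim_value = -1000))
  ct <- ph$ct
  fld <- radial_warp(ct, ph$masks$head, amp = 3, sigma_vox = 12, seed = 77)
  dt <- diffeo_transform(fld, neotemplate:::invert_field(fld, ct), ct)
  mv <- apply_transform(ct, dt, fill = -1000)

  ab <- syn_register(mv, ct, metric = "CC", params = fast_syn())
  ba <- syn_register(ct, mv, metric = "CC", params = fast_syn())

  hd <- which(ph$masks$head$data == 1)
  X <- neotemplate:::voxel_centers_world(ct)[hd, ][seq(1, length(hd), 23), ]
  h <- min(ct$spacing)
  # symmetry: the two directions compose to the identity
  sym <- sqrt(rowSums((map_points(ba, map_points(ab, X)) - X)^2)) / h
  expect_lt(mean(sym), 0.2)
  # inverse consistency of a single result
  ic <- sqrt(rowSums((map_points(ab, map_points(ab, X), inverse = TRUE) -
                        X)^2)) / h
  expect_lt(mean(ic), 0.1)
  expect_lt(max(ic), 0.5)
  # diffeomorphism: positive Jacobian on the foreground
  jd <- jacobian_determinant(ab$forward, ct)
  expect_gt(min(jd[ph$masks$head$data == 1]), 0)
  # similarity strictly improves over the affine (identity) baseline
  warped <- apply_transform(mv, ab, fill = -1000)
  expect_gt(cross_correlation(ct, warped), cross_correlation(ct, mv))
})

test_that("multimodal diffeomorphic registration (MI remap) improves CT-MR
           alignment", {
  ph <- generate_head_phantom(mid_spec(nuisance_blobs = 0L,
                                       rim_value = -1000))
  ct <- transform_ct_intensity(cleaned_ct(ph))
  mr <- ph$mr
  fld <- radial_warp(ct, ph$masks$head, amp = 2.5, sigma_vox = 12, seed = 78)
  dt <- diffeo_transform(fld, neotemplate:::invert_field(fld, ct), ct)
  ct_w <- apply_transform(ct, dt, fill = 0)
  est <- syn_register(ct_w, mr, metric = "MI", params = fast_syn())
  aligned <- apply_transform(ct_w, est, fill = 0)
  expect_gt(mutual_information(aligned, mr, bins = 32),
            mutual_information(ct_w, mr, bins = 32))
})

test_that("affine result agrees with an independent registration toolkit", {
  ph <- generate_head_phantom(tiny_spec(nuisance_blobs = 0L,
                                        rim_value = -1000))
  ct <- ph$ct
  shift <- affine_transform(diag(3), c(9, -5, 3))
  mv <- apply_transform(ct, shift, fill = -1000)
  dir <- file.path(tempdir(), "sitk")
  dir.create(dir, showWarnings = FALSE)
  write_volume(ct, file.path(dir, "fixed.nii.gz"))
  write_volume(mv, file.path(dir, "moving.nii.gz"))
  py <- file.path(dir, "reg.py")
  writeLines(c(
    "import SimpleITK as sitk",
    sprintf("fixed = sitk.ReadImage(r'%s', sitk.sitkFloat64)",
            file.path(dir, "fixed.nii.gz")),
    sprintf("moving = sitk.ReadImage(r'%s', sitk.sitkFloat64)",
            file.path(dir, "moving.nii.gz")),
    "reg = sitk.ImageRegistrationMethod()",
    "reg.SetMetricAsMeanSquares()",
    "reg.SetOptimizerAsRegularStepGradientDescent(4.0, 0.005, 300)",
    "reg.SetInterpolator(sitk.sitkLinear)",
    "reg.SetInitialTransform(sitk.TranslationTransform(3), inPlace=True)",
    "reg.SetShrinkFactorsPerLevel([4, 2, 1])",
    "reg.SetSmoothingSigmasPerLevel([2, 1, 0])",
    "out = reg.Execute(fixed, moving)",
    "print('PARAMS', *out.GetParameters())"
  ), py)
  res <- suppressWarnings(system2("python", py, stdout = TRUE, stderr = TRUE))
  line <- grep("^PARAMS", res, value = TRUE)
  expect_length(line, 1)
  sitk_t <- as.numeric(strsplit(line, " ")[[1]][-1])
  # SimpleITK's transform maps fixed physical points to moving points, the
  # same pull-back convention used here, but in LPS coordinates: the x and y
  # axes are flipped relative to our RAS frame
  sitk_t_ras <- sitk_t * c(-1, -1, 1)
  est <- affine_register(mv, ct, metric = "CC", params = fast_affine())
  expect_lt(max(abs(est$translation - sitk_t_ras)) / min(ct$spacing), 1)
})
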