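# Synthetic phantom generator: determinism, anatomy invariants, populations.

test_that("phantom_spec validates its fields", {
  expect_error(phantom_spec(tissue_hu = list(air = -1000, csf = 15, wm = 25,
                                             gm = 40, bone = 4000, scalp = 60)),
               "plausible")
  expect_error(phantom_spec(skull_thickness = 100), "skull_thickness")
  expect_error(phantom_spec(fontanel_gaps = list(list(dir = c(0, 0, 1),
                                                      width = 95))),
               "widths")
  expect_error(phantom_spec(head_radii = c(80, 80, 80)), "exceed")
})

test_that("same spec and seed give a bitwise-identical phantom", {
  a <- generate_head_phantom(tiny_spec(seed = 11L))
  b <- generate_head_phantom(tiny_spec(seed = 11L))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$mr$data, b$mr$data)
  for (nm in names(a$masks))
    expect_identical(a$masks[[nm]]$data, b$masks[[nm]]$data)
  c <- generate_head_phantom(tiny_spec(seed = 12L))
  expect_false(identical(a$ct$data, c$ct$data))
})

test_that("phantom anatomy satisfies the mask invariants", {
  ph <- generate_head_phantom(desk_spec())
  m <- ph$masks
  # nesting: brain within intracranial within head
  expect_true(all(m$brain$data <= m$intracranial$data))
  expect_true(all(m$intracranial$data <= m$head$data))
  # fontanels disjoint from bone, on the shell between intracranial and head
  expect_equal(sum(m$fontanels$data * m$skull$data), 0)
  expect_equal(sum(m$fontanels$data * m$intracranial$data), 0)
  expect_true(all(m$fontanels$data <= m$head$data))
  # intracranial = head minus the geometric scalp and bone shells
  recon <- m$head$data * (1 - m$scalp_shell$data) *
    (1 - m$skull$data) * (1 - m$fontanels$data)
  expect_identical(recon, m$intracranial$data)
  # intensities: bone bright, air dark
  expect_true(all(ph$ct$data[m$skull$data == 1] >= 500))
  out_head <- ph$ct$data[m$head$data == 0]
  expect_true(mean(out_head <= -900) > 0.9)  # air except rim/blobs
})

test_that("two fontanel gaps produce two shell components and CT has
           air/bone modes", {
  ph <- generate_head_phantom(desk_spec())
  expect_equal(mask_n_components(ph$masks$fontanels), 2)
  # histogram modes near -1000 and +1000
  h <- hist(ph$ct$data, breaks = seq(-3100, 1100, by = 50), plot = FALSE)
  cen <- h$mids
  air_peak <- cen[which.max(h$counts)]
  expect_lt(abs(air_peak - -1000), 60)
  bone_win <- h$counts[cen > 800 & cen < 1200]
  local_win <- h$counts[cen > 300 & cen < 800]
  expect_gt(max(bone_win), max(local_win))
  # rim present at the rim value
  expect_lt(min(ph$ct$data), -2900)
})

test_that("population generation: zero perturbation reproduces the mean
           phantom; subjects are distinct, reproducible, and diffeomorphic", {
  spec <- tiny_spec(seed = 5L)
  one <- generate_population(spec, n = 1, rigid_sd = c(0, 0), warp_sd = 0,
                             seed = 5L)
  ref <- generate_head_phantom(phantom_spec(
    grid_shape = spec$grid_shape, spacing = spec$spacing,
    skull_thickness = spec$skull_thickness,
    csf_thickness = spec$csf_thickness, gm_thickness = spec$gm_thickness,
    scalp_thickness = spec$scalp_thickness, seed = 5L * 1000L + 1L))
  expect_identical(one[[1]]$ct$data, ref$ct$data)

  pop <- generate_population(spec, n = 4, rigid_sd = c(2, 2), warp_sd = 2,
                             warp_smoothness = 12, seed = 9L)
  for (i in 1:3)
    for (j in (i + 1):4)
      expect_false(identical(pop[[i]]$ct$data, pop[[j]]$ct$data))
  pop2 <- generate_population(spec, n = 4, rigid_sd = c(2, 2), warp_sd = 2,
                              warp_smoothness = 12, seed = 9L)
  expect_identical(pop[[2]]$ct$data, pop2[[2]]$ct$data)

  # every generated warp is diffeomorphic (positive Jacobian)
  for (s in pop) {
    dif <- s$true_transform$transforms[[2]]
    expect_s3_class(dif, "nt_diffeo")
    jd <- jacobian_determinant(dif$forward, s$ct)
    expect_gt(min(jd), 0)
  }
})

test_that("ground-truth masks transform consistently with true_transform", {
  spec <- tiny_spec(seed = 2L)
  mean_masks <- generate_head_phantom(
    phantom_spec(grid_shape = spec$grid_shape, spacing = spec$spacing,
                 skull_thickness = spec$skull_thickness,
                 csf_thickness = spec$csf_thickness,
                 gm_thickness = spec$gm_thickness,
                 scalp_thickness = spec$scalp_thickness))$masks
  pop <- generate_population(spec, n = 2, rigid_sd = c(2, 2), warp_sd = 2,
                             warp_smoothness = 12, seed = 21L)
  for (s in pop) {
    warped <- apply_transform(mean_masks$head, s$true_transform,
                              interp = "nearest", fill = 0, ref = s$ct)
    expect_gte(dice(warped, s$masks$head), 0.95)
  }
})

test_that("phantom sets round-trip through disk with a JSON sidecar", {
  ph <- generate_head_phantom(tiny_spec(seed = 3L))
  dir <- file.path(tempdir(), "phantom-out")
  write_phantom(ph, dir)
  ct2 <- read_volume(file.path(dir, "ct.nii.gz"))
  expect_identical(ct2$data, ph$ct$data)
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 3)
  expect_equal(meta$tissue_hu$bone, 1000)
  m <- read_mask(file.path(dir, "mask_intracranial.nii.gz"))
  expect_identical(m$data, ph$masks$intracranial$data)
})
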