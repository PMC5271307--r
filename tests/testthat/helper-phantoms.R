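# Shared fixtures: phantoms are generated in code, sized for fast tests.

# small, fast phantom (32^3, 4 mm): coarse but renders all structures
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), spacing = c(4, 4, 4),
               skull_thickness = 8, csf_thickness = 5, gm_thickness = 8,
               scalp_thickness = 5, ...)
}

# mid-size phantom (48^3, 2.5 mm) used by segmentation/registration tests;
# the bone shell is kept at 2.4+ voxels so its voxelization stays watertight
mid_spec <- function(...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), spacing = c(2.5, 2.5, 2.5),
               skull_thickness = 6, ...)
}

# standard desk-scale phantom (64^3, 2 mm)
desk_spec <- function(...) phantom_spec(...)

# preprocessed (cleaned, HU scale) CT of a phantom set
cleaned_ct <- function(ph) clean_background(ph$ct, ph$masks$head)

# spherical high-resolution phantom for warp-recovery tests (1 mm voxels)
sphere_spec <- function(...) {
  phantom_spec(grid_shape = c(72L, 72L, 72L), spacing = c(1, 1, 1),
               head_radii = c(29, 29, 29), scalp_thickness = 3,
               skull_thickness = 3.5, csf_thickness = 2.5, gm_thickness = 4,
               nuisance_blobs = 0L, rim_value = -1000, ...)
}

# smooth radial ground-truth warp on a spherical phantom grid: observable by
# intensity registration (normal to the nested shells), diffeomorphic
radial_warp <- function(geom, head_mask, amp = 4.2, sigma_vox = 24,
                        seed = 43) {
  d <- dim(geom$data)
  ctr <- (d - 1) / 2 * geom$spacing
  X <- neotemplate:::voxel_centers_world(geom)
  Xc <- sweep(X, 2, ctr, "-")
  r <- sqrt(rowSums(Xc^2))
  rhat <- Xc / pmax(r, 1e-6)
  hd <- head_mask$data == 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- array(rnorm(prod(d)), d)
  s <- array(neotemplate:::cpp_gauss3d(as.double(s), as.integer(d),
                                       rep(sigma_vox, 3), 1L), d)
  s <- s / sqrt(mean(s[hd]^2)) * amp
  w <- pmin(1, r / 12) * exp(-pmax(0, r - 34) / 10)
  array(rhat * (as.vector(s) * w), c(d, 3))
}

# landmarks at strong-gradient voxels inside the head (world coords)
gradient_landmarks <- function(vol, head_mask, n = 200, seed = 7) {
  d <- dim(vol$data)
  G <- neotemplate:::cpp_gradient3d(as.double(vol$data), as.integer(d),
                                    as.double(vol$spacing))
  gm <- sqrt(rowSums(G^2))
  hd <- head_mask$data == 1
  cand <- which(hd & gm > stats::quantile(gm[hd], 0.8))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample(cand, n)
  neotemplate:::voxel_centers_world(vol)[idx, , drop = FALSE]
}

# light registration settings for small-grid tests
fast_affine <- function() affine_params(levels = c(4, 2), iters = c(150, 80))
fast_syn <- function() syn_params(levels = c(4, 2), iters = c(40, 25))
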