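# ---- Synthetic neonatal head phantoms -----------------------------------------
#
# Nested-ellipsoid head model: scalp, cranial bone shell with fontanel/suture
# gaps cut as angular sectors, a CSF rim, and a brain core (gray-matter shell
# around white matter). The CT rendering adds extracranial nuisance blobs
# (pillow/pacifier), an artificial sub-air rim, and Gaussian noise; the
# MR-like rendering inverts the bone/soft-tissue contrast (bone dark, brain
# mid-bright) as in T1-weighted images.

#' Phantom specification
#'
#' @param grid_shape Integer length-3, voxel counts.
#' @param spacing Numeric length-3, mm per voxel.
#' @param head_radii Numeric length-3, outer head semi-axes in mm.
#' @param scalp_thickness Scalp shell thickness, mm.
#' @param skull_thickness Cranial bone shell thickness, mm. The default is
#'   thicker than a real neonatal calvarium so the voxelized shell stays
#'   watertight on the coarse desk-scale grid; what matters downstream is
#'   the hard-shell-with-gaps topology, not the literal thickness.
#' @param csf_thickness CSF rim thickness under the skull, mm.
#' @param gm_thickness Gray-matter shell thickness, mm.
#' @param fontanel_gaps List of gaps, each `list(dir = <length-3>, width =
#'   <degrees>)`: an angular sector of the bone shell (about the head center,
#'   around `dir`) replaced by membranous soft tissue. Widths must lie in
#'   (0, 90).
#' @param tissue_hu Named list of CT intensities (HU) for `air`, `csf`, `wm`,
#'   `gm`, `bone`, `scalp`, following the usual Hounsfield calibration
#'   (air -1000, water 0, CSF ~15, WM ~20-30, GM ~37-45, bone +1000).
#' @param tissue_mr Named list of MR-like intensities (arbitrary units,
#'   0-1023) for the same tissues plus `fontanel`.
#' @param noise_sd CT additive Gaussian noise sd, HU.
#' @param mr_noise_sd MR additive Gaussian noise sd.
#' @param rim_value Intensity of the artificial rim surrounding the air
#'   region, HU.
#' @param nuisance_blobs Number of extracranial nuisance blobs.
#' @param seed Integer RNG seed; the phantom is a deterministic function of
#'   the spec.
#' @return A `phantom_spec` object (a validated list).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(2, 2, 2),
                         head_radii = c(42, 52, 45),
                         scalp_thickness = 4,
                         skull_thickness = 5,
                         csf_thickness = 3,
                         gm_thickness = 5,
                         fontanel_gaps = list(
                           list(dir = c(0, 0, 1), width = 30),
                           list(dir = c(0, 1, 0.6), width = 22)),
                         tissue_hu = list(air = -1000, csf = 15, wm = 25,
                                          gm = 40, bone = 1000, scalp = 60),
                         tissue_mr = list(air = 15, csf = 250, wm = 620,
                                          gm = 460, bone = 130, scalp = 550,
                                          fontanel = 350),
                         noise_sd = 10,
                         mr_noise_sd = 15,
                         rim_value = -3000,
                         nuisance_blobs = 2L,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               head_radii = as.numeric(head_radii),
               scalp_thickness = scalp_thickness,
               skull_thickness = skull_thickness,
               csf_thickness = csf_thickness, gm_thickness = gm_thickness,
               fontanel_gaps = fontanel_gaps, tissue_hu = tissue_hu,
               tissue_mr = tissue_mr, noise_sd = noise_sd,
               mr_noise_sd = mr_noise_sd, rim_value = rim_value,
               nuisance_blobs = as.integer(nuisance_blobs),
               seed = as.integer(seed))
  hu <- unlist(spec$tissue_hu)
  if (any(hu < -3100 | hu > 3100))
    stop("tissue_hu outside plausible CT range [-3100, 3100]", call. = FALSE)
  if (spec$skull_thickness >= min(spec$head_radii))
    stop("skull_thickness must be smaller than min(head_radii)", call. = FALSE)
  for (g in spec$fontanel_gaps)
    if (g$width <= 0 || g$width >= 90)
      stop("fontanel angular widths must lie in (0, 90) degrees", call. = FALSE)
  if (any(spec$head_radii >= spec$grid_shape * spec$spacing / 2))
    stop("head radii exceed the grid extent", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# run `expr` under a local RNG stream; restores global .Random.seed
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# label codes
PHANTOM_LABELS <- c(air = 0L, scalp = 1L, bone = 2L, fontanel = 3L,
                    csf = 4L, gm = 5L, wm = 6L)

# noise-free anatomy: label volume + ground-truth masks (no RNG involved)
phantom_anatomy <- function(spec) {
  d <- spec$grid_shape
  geom <- volume(array(0, d), spacing = spec$spacing)
  center <- (d - 1) / 2 * spec$spacing
  X <- sweep(voxel_centers_world(geom), 2, center, "-")
  erho <- function(radii) {
    radii <- pmax(radii, 1e-6)
    sqrt((X[, 1] / radii[1])^2 + (X[, 2] / radii[2])^2 + (X[, 3] / radii[3])^2)
  }
  r_head <- spec$head_radii
  r_scalp_in <- r_head - spec$scalp_thickness
  r_skull_in <- r_scalp_in - spec$skull_thickness
  r_csf_in <- r_skull_in - spec$csf_thickness
  r_gm_in <- r_csf_in - spec$gm_thickness
  rho_head <- erho(r_head)
  rho_scalp_in <- erho(r_scalp_in)
  rho_skull_in <- erho(r_skull_in)
  rho_csf_in <- erho(r_csf_in)
  rho_gm_in <- erho(r_gm_in)

  lab <- integer(prod(d))                      # air
  lab[rho_head <= 1] <- PHANTOM_LABELS["scalp"]
  shell <- rho_scalp_in <= 1 & rho_skull_in > 1
  lab[shell] <- PHANTOM_LABELS["bone"]
  lab[rho_skull_in <= 1] <- PHANTOM_LABELS["csf"]
  lab[rho_csf_in <= 1] <- PHANTOM_LABELS["gm"]
  lab[rho_gm_in <= 1] <- PHANTOM_LABELS["wm"]

  # fontanel/suture gaps: angular sectors of the bone shell become membrane
  nrm <- sqrt(rowSums(X^2)); nrm[nrm == 0] <- 1
  font <- logical(prod(d))
  for (g in spec$fontanel_gaps) {
    u <- g$dir / sqrt(sum(g$dir^2))
    ang <- acos(pmin(1, pmax(-1, (X %*% u) / nrm))) * 180 / pi
    font <- font | (shell & ang <= g$width / 2)
  }
  lab[font] <- PHANTOM_LABELS["fontanel"]

  mk <- function(sel) with_data(geom, as.numeric(sel), mask = TRUE)
  list(labels = with_data(geom, lab),
       center = center,
       masks = list(head = mk(rho_head <= 1),
                    scalp_shell = mk(rho_head <= 1 & rho_scalp_in > 1),
                    skull = mk(shell & !font),
                    fontanels = mk(font),
                    intracranial = mk(rho_skull_in <= 1),
                    brain = mk(rho_csf_in <= 1),
                    csf = mk(rho_skull_in <= 1 & rho_csf_in > 1)))
}

render_ct <- function(labels, spec) {
  hu <- spec$tissue_hu
  lut <- c(hu$air, hu$scalp, hu$bone, hu$csf * 2, hu$csf, hu$gm, hu$wm)
  # fontanel membrane: soft tissue, ~2x CSF (label order: air scalp bone
  # fontanel csf gm wm)
  with_data(labels, lut[as.vector(labels$data) + 1L])
}

render_mr <- function(labels, spec) {
  m <- spec$tissue_mr
  lut <- c(m$air, m$scalp, m$bone, m$fontanel, m$csf, m$gm, m$wm)
  with_data(labels, lut[as.vector(labels$data) + 1L])
}

# rim + blobs + noise; uses the current RNG stream
decorate_ct <- function(ct, head, spec) {
  d <- vol_dim(ct)
  center <- (d - 1) / 2 * spec$spacing
  X <- sweep(voxel_centers_world(ct), 2, center, "-")
  r <- sqrt(rowSums(X^2))
  out <- as.vector(ct$data)
  outside <- as.vector(head$data) == 0
  # nuisance blobs (pillow / pacifier) strictly outside the head
  if (spec$nuisance_blobs > 0) {
    rho_head <- sqrt((X[, 1] / spec$head_radii[1])^2 +
                     (X[, 2] / spec$head_radii[2])^2 +
                     (X[, 3] / spec$head_radii[3])^2)
    for (b in seq_len(spec$nuisance_blobs)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      scale_r <- runif(1, 1.25, 1.45)
      pos <- u * spec$head_radii * scale_r
      brad <- runif(1, 6, 10)
      val <- sample(c(-300, 100, 150), 1)   # foam pillow / plastic
      db <- sqrt(rowSums(sweep(X, 2, pos, "-")^2))
      sel <- db <= brad & rho_head > 1.12
      out[sel] <- val
    }
  }
  # artificial rim around the air: thin spherical shell near the grid edge
  rim_r <- min(d * spec$spacing) / 2 - 2 * max(spec$spacing)
  rim <- abs(r - rim_r) <= max(spec$spacing) * 0.75 & outside
  out[rim] <- spec$rim_value
  if (spec$noise_sd > 0)
    out <- out + rnorm(length(out), sd = spec$noise_sd)
  with_data(ct, out)
}

#' Generate a synthetic neonatal head phantom
#'
#' Builds a paired CT (HU) and MR-like volume from a nested-ellipsoid head
#' anatomy, with ground-truth masks. The CT includes extracranial nuisance
#' blobs, an artificial rim at `rim_value` around the air region, and additive
#' Gaussian noise; all randomness is driven by `spec$seed`, so the result is a
#' deterministic function of the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_set`: list with `ct`, `mr`, `masks` (head, skull,
#'   fontanels, intracranial, brain, csf, scalp_shell), `true_transform`
#'   (identity for a single phantom), and `spec`.
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- phantom_anatomy(spec)
  with_seed(spec$seed, {
    ct <- decorate_ct(render_ct(anat$labels, spec), anat$masks$head, spec)
    mr0 <- render_mr(anat$labels, spec)
    mr <- with_data(mr0, pmax(0, as.vector(mr0$data) +
                                   rnorm(prod(vol_dim(mr0)),
                                         sd = spec$mr_noise_sd)))
    structure(list(ct = ct, mr = mr, masks = anat$masks,
                   true_transform = identity_transform(), spec = spec),
              class = "phantom_set")
  })
}

# random smooth displacement field with positive Jacobian; RMS magnitude
# warp_sd mm, correlation length warp_smoothness mm
random_smooth_field <- function(geom, warp_sd, warp_smoothness, max_tries = 6) {
  d <- vol_dim(geom)
  fld <- array(rnorm(prod(d) * 3), c(d, 3))
  sig_vox <- rep(warp_smoothness, 3) / geom$spacing
  fld <- smooth_field(fld, sig_vox, zeropad = TRUE)
  rms <- sqrt(mean(fld^2) * 3)
  fld <- fld * (warp_sd / max(rms, 1e-12))
  amp <- 1
  for (i in seq_len(max_tries)) {
    jd <- jacobian_determinant(fld * amp, geom)
    if (min(jd) > 0.05) return(fld * amp)
    amp <- amp * 0.7
    message("damping warp amplitude to keep the field diffeomorphic (x",
            format(amp, digits = 3), ")")
  }
  fld * amp
}

#' Generate a population of phantom subjects around a mean anatomy
#'
#' Each subject is the mean anatomy moved by a random rigid transform composed
#' with a smooth random diffeomorphic warp, then re-rendered with its own
#' noise, rim, and nuisance structures. Every subject carries the generating
#' transform from the mean anatomy as ground truth.
#'
#' @param mean_spec [phantom_spec()] of the mean anatomy.
#' @param n Number of subjects (>= 1).
#' @param rigid_sd Length-2: sd of random translations (mm) and rotations
#'   (degrees).
#' @param warp_sd RMS magnitude of the random warp, mm.
#' @param warp_smoothness Correlation length of the random warp, mm.
#' @param seed Integer seed for the population.
#' @return List of `phantom_set` objects.
#' @export
generate_population <- function(mean_spec, n, rigid_sd = c(2, 2), warp_sd = 2,
                                warp_smoothness = 12, seed = 1L) {
  stopifnot(inherits(mean_spec, "phantom_spec"), n >= 1)
  anat <- phantom_anatomy(mean_spec)
  geom <- anat$labels
  center <- anat$center
  ct0 <- render_ct(anat$labels, mean_spec)
  mr0 <- render_mr(anat$labels, mean_spec)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- with_seed(seed * 1000L + i, {
      zero <- all(rigid_sd == 0) && warp_sd == 0
      if (zero) {
        tr <- identity_transform()
        ct_i <- ct0; mr_i <- mr0; masks_i <- anat$masks
      } else {
        tvec <- rnorm(3, sd = rigid_sd[1])
        ang <- rnorm(3, sd = rigid_sd[2]) * pi / 180
        Rx <- rot3(1, ang[1]); Ry <- rot3(2, ang[2]); Rz <- rot3(3, ang[3])
        R <- Rz %*% Ry %*% Rx
        rigid <- affine_transform(R, as.numeric(center - R %*% center) + tvec)
        fwd <- if (warp_sd > 0)
          random_smooth_field(geom, warp_sd, warp_smoothness)
        else array(0, c(vol_dim(geom), 3))
        diffeo <- diffeo_transform(fwd, invert_field(fwd, geom), geom)
        tr <- compose_transforms(list(rigid, diffeo))
        ct_i <- apply_transform(ct0, tr, interp = "linear",
                                fill = mean_spec$tissue_hu$air, ref = geom)
        mr_i <- apply_transform(mr0, tr, interp = "linear",
                                fill = mean_spec$tissue_mr$air, ref = geom)
        masks_i <- lapply(anat$masks, apply_transform, t = tr,
                          interp = "nearest", fill = 0, ref = geom)
      }
      ct_i <- decorate_ct(ct_i, masks_i$head, mean_spec)
      mr_i <- with_data(mr_i, pmax(0, as.vector(mr_i$data) +
                                        rnorm(prod(vol_dim(mr_i)),
                                              sd = mean_spec$mr_noise_sd)))
      structure(list(ct = ct_i, mr = mr_i, masks = masks_i,
                     true_transform = tr, spec = mean_spec),
                class = "phantom_set")
    })
  }
  subjects
}

rot3 <- function(axis, theta) {
  c3 <- cos(theta); s3 <- sin(theta)
  if (axis == 1) matrix(c(1, 0, 0, 0, c3, s3, 0, -s3, c3), 3, 3)
  else if (axis == 2) matrix(c(c3, 0, -s3, 0, 1, 0, s3, 0, c3), 3, 3)
  else matrix(c(c3, s3, 0, -s3, c3, 0, 0, 0, 1), 3, 3)
}

#' Write a phantom set to disk
#'
#' Writes CT, MR, and all masks as NIfTI files plus a JSON sidecar recording
#' the generating spec and seed.
#'
#' @param set A `phantom_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(set$ct, file.path(dir, "ct.nii.gz"))
  write_volume(set$mr, file.path(dir, "mr.nii.gz"))
  for (nm in names(set$masks))
    write_volume(set$masks[[nm]], file.path(dir, paste0("mask_", nm, ".nii.gz")))
  sp <- set$spec
  sp$fontanel_gaps <- lapply(sp$fontanel_gaps, function(g)
    list(dir = g$dir, width = g$width))
  jsonlite::write_json(unclass(sp), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
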