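# ---- Coupled level-set intracranial extraction --------------------------------
#
# A pair of surfaces evolves as geodesic active regions on the preprocessed
# CT: the exterior surface starts at the head boundary and propagates inward,
# the interior surface starts from a deeply eroded head seed and propagates
# outward. Both are driven by a balloon force gated by (a) a bone-region term
# that vanishes inside cranial bone, (b) an edge-stopping function
# g = 1/(1 + |grad(G_sigma * I)|^2 / lambda^2), and (c) a mutual soft gate
# that vanishes as the two surfaces approach within a touch distance, so that
# where bone is absent (fontanels, sutures) the surfaces meet and stall
# without crossing. Non-crossing (interior inside exterior) is additionally
# enforced by projection after every step. Level sets are kept close to
# signed distance by periodic reinitialization via exact Euclidean distance
# transforms.

#' Default coupled level-set parameters
#'
#' @param speed Balloon speed weight (dimensionless; the CFL step adapts to
#'   it).
#' @param curvature Curvature regularization weight.
#' @param edge_attraction Weight of the edge-attraction (advection) term.
#' @param edge_balloon_mix Fraction of the balloon speed modulated by the
#'   edge-stopping function g (the remainder is gated by the bone-region
#'   term only, so weak-gradient plateaus cannot stall the fronts).
#' @param touch_mm Coupling distance: surfaces closer than this stop moving
#'   toward each other.
#' @param bone_threshold Intensity above which a voxel counts as cranial
#'   bone (HU scale; pass the transformed-scale equivalent when working on
#'   intensity-transformed CT).
#' @param sigma_mm Gaussian pre-smoothing of the image for the edge map, mm.
#' @param lambda Edge contrast scale; `NULL` picks it from the gradient
#'   magnitude distribution.
#' @param dt_factor CFL fraction of the voxel size per iteration.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance: mean absolute level-set change (mm) on
#'   the narrow band per iteration.
#' @param reinit_every Reinitialize signed distances every this many
#'   iterations.
#' @param bone_sigma_vox Smoothing (voxels) of the bone indicator before it
#'   gates the balloon speed.
#' @param bone_gate_gain Gain of the bone gate: the balloon stops where the
#'   smoothed bone indicator exceeds 1/gain.
#' @param band_mm Narrow-band half-width used for convergence monitoring.
#' @return Named list of parameters.
#' @export
levelset_params <- function(speed = 1.0, curvature = 0.2,
                            edge_attraction = 0.5, edge_balloon_mix = 0.25,
                            touch_mm = NULL,
                            bone_threshold = 300, sigma_mm = NULL,
                            lambda = NULL, dt_factor = 0.45, max_iter = 150,
                            tol = 2e-3, reinit_every = 10, band_mm = NULL,
                            bone_sigma_vox = 0.8, bone_gate_gain = 1.5) {
  list(speed = speed, curvature = curvature,
       edge_attraction = edge_attraction,
       edge_balloon_mix = edge_balloon_mix, touch_mm = touch_mm,
       bone_threshold = bone_threshold, sigma_mm = sigma_mm, lambda = lambda,
       dt_factor = dt_factor, max_iter = max_iter, tol = tol,
       reinit_every = reinit_every, band_mm = band_mm,
       bone_sigma_vox = bone_sigma_vox, bone_gate_gain = bone_gate_gain)
}

# signed Euclidean distance to the boundary of mask (negative inside)
signed_distance <- function(mask_data, dims, spacing) {
  inside <- as.integer(mask_data != 0)
  d_to_in <- cpp_edt3d(inside, as.integer(dims), as.double(spacing))
  d_to_out <- cpp_edt3d(1L - inside, as.integer(dims), as.double(spacing))
  d_to_in - d_to_out
}

#' Initialize the coupled surface pair
#'
#' The exterior surface starts at the head boundary; the interior surface is
#' the head eroded by `inner_erosion_mm`, placing it strictly inside the
#' intracranial cavity. Both are represented as signed-distance functions
#' (negative inside).
#'
#' @param ct Preprocessed CT volume (cleaned background).
#' @param head Binary head mask.
#' @param inner_erosion_mm Erosion depth for the interior seed, mm.
#' @return A `levelset_pair`: signed-distance volumes `phi_in`, `phi_out`,
#'   the iteration counter, and a `touched` indicator volume.
#' @export
init_coupled_surfaces <- function(ct, head, inner_erosion_mm = 12) {
  stop_if_grid_mismatch(ct, head)
  if (sum(head$data) == 0)
    stop("empty head mask", call. = FALSE)
  seed <- mask_erode(head, inner_erosion_mm)
  if (sum(seed$data) == 0)
    stop("inner erosion removed the entire interior seed", call. = FALSE)
  d <- vol_dim(ct)
  phi_out <- with_data(ct, signed_distance(head$data, d, ct$spacing))
  phi_in <- with_data(ct, signed_distance(seed$data, d, ct$spacing))
  structure(list(phi_in = phi_in, phi_out = phi_out, iteration = 0L,
                 touched = with_data(ct, array(0, d)),
                 trace = NULL),
            class = "levelset_pair")
}

# Godunov upwind gradient norms for phi_t + F|grad phi| = 0
upwind_norms <- function(os) {
  dxm <- os[, 1]; dxp <- os[, 2]; dym <- os[, 3]; dyp <- os[, 4]
  dzm <- os[, 5]; dzp <- os[, 6]
  gp <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 +
             pmax(dym, 0)^2 + pmin(dyp, 0)^2 +
             pmax(dzm, 0)^2 + pmin(dzp, 0)^2)
  gm <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 +
             pmin(dym, 0)^2 + pmax(dyp, 0)^2 +
             pmin(dzm, 0)^2 + pmax(dzp, 0)^2)
  list(plus = gp, minus = gm)
}

# vanishes once the inter-surface distance falls below half the touch
# distance, reaches full speed at 1.5x the touch distance
soft_gate <- function(dist_mm, touch_mm) pmin(1, pmax(0, dist_mm / touch_mm - 0.5))

#' Evolve the coupled level sets
#'
#' Runs the coupled geodesic-active-region evolution until the mean level-set
#' change on the narrow band drops below `tol` or `max_iter` is reached (the
#' latter raises a convergence warning but still returns the state).
#'
#' @param ct Preprocessed CT (background cleaned; HU or transformed scale,
#'   with `bone_threshold` set accordingly).
#' @param pair A `levelset_pair` from [init_coupled_surfaces()].
#' @param params Parameters from [levelset_params()].
#' @return The evolved `levelset_pair`, with an iteration trace data frame
#'   (`iteration`, `band_change`, `touched`, `min_separation`) attached as
#'   `$trace`.
#' @export
evolve_coupled_levelsets <- function(ct, pair, params = levelset_params()) {
  evolve_levelsets_impl(ct, pair, params, coupled = TRUE)
}

#' Evolve a single (uncoupled) geodesic active surface
#'
#' The interior surface alone, with the mutual coupling disabled; used to
#' check that on gap-free skulls the coupling is immaterial.
#'
#' @inheritParams evolve_coupled_levelsets
#' @return The evolved `levelset_pair` (the exterior surface is left fixed).
#' @export
evolve_single_levelset <- function(ct, pair, params = levelset_params()) {
  evolve_levelsets_impl(ct, pair, params, coupled = FALSE)
}

evolve_levelsets_impl <- function(ct, pair, params, coupled) {
  d <- vol_dim(ct)
  sp <- ct$spacing
  h <- min(sp)
  p <- params
  if (is.null(p$touch_mm)) p$touch_mm <- 1.0 * h
  if (is.null(p$sigma_mm)) p$sigma_mm <- h
  if (is.null(p$band_mm)) p$band_mm <- 3 * h

  # edge-stopping function on the smoothed image
  Is <- gaussian_smooth(ct, p$sigma_mm * 2 * sqrt(2 * log(2)))
  G <- cpp_gradient3d(as.double(Is$data), as.integer(d), as.double(sp))
  gmag <- sqrt(rowSums(G^2))
  lambda <- p$lambda
  if (is.null(lambda)) {
    pos <- gmag[gmag > 0]
    lambda <- if (length(pos)) stats::quantile(pos, 0.98) / 3 else 1
  }
  g_edge <- 1 / (1 + (gmag / lambda)^2)
  gx <- cpp_gradient3d(g_edge, as.integer(d), as.double(sp))

  # bone-region gate: balloon speed vanishes inside cranial bone; thresholded
  # on the unsmoothed image so bone intensity does not bleed into neighbors
  bone <- as.numeric(as.vector(ct$data) > p$bone_threshold)
  bone_s <- cpp_gauss3d(bone, as.integer(d), as.double(rep(p$bone_sigma_vox, 3)))
  region_gate <- pmin(1, pmax(0, 1 - bone_s * p$bone_gate_gain))

  stop_field <- region_gate *
    ((1 - p$edge_balloon_mix) + p$edge_balloon_mix * g_edge)

  phi_in <- as.vector(pair$phi_in$data)
  phi_out <- as.vector(pair$phi_out$data)
  dt <- p$dt_factor * h / max(p$speed, 1e-6)
  trace <- vector("list", p$max_iter)
  converged <- FALSE
  still_streak <- 0
  it <- 0L
  while (it < p$max_iter) {
    it <- it + 1L
    os_in <- cpp_onesided3d(phi_in, as.integer(d), as.double(sp))
    # interior surface: balloon outward (expansion), gated near the exterior
    gate_in <- if (coupled) soft_gate(-phi_out, p$touch_mm) else 1
    F_in <- p$speed * stop_field * gate_in
    un_in <- upwind_norms(os_in)
    lap_in <- (os_in[, 2] - os_in[, 1]) / sp[1] +
      (os_in[, 4] - os_in[, 3]) / sp[2] + (os_in[, 6] - os_in[, 5]) / sp[3]
    cgrad_in <- cbind((os_in[, 1] + os_in[, 2]) / 2,
                      (os_in[, 3] + os_in[, 4]) / 2,
                      (os_in[, 5] + os_in[, 6]) / 2)
    adv_in <- rowSums(gx * cgrad_in)
    # expansion: outward speed +F  ->  phi_t = -F |grad phi| (Godunov)
    dphi_in <- dt * (-(pmax(F_in, 0) * un_in$plus + pmin(F_in, 0) * un_in$minus) +
                       p$curvature * g_edge * lap_in +
                       p$edge_attraction * adv_in)
    new_in <- phi_in + dphi_in

    if (coupled) {
      os_out <- cpp_onesided3d(phi_out, as.integer(d), as.double(sp))
      gate_out <- soft_gate(phi_in, p$touch_mm)
      F_out <- -p$speed * stop_field * gate_out   # inward motion
      un_out <- upwind_norms(os_out)
      lap_out <- (os_out[, 2] - os_out[, 1]) / sp[1] +
        (os_out[, 4] - os_out[, 3]) / sp[2] + (os_out[, 6] - os_out[, 5]) / sp[3]
      cgrad_out <- cbind((os_out[, 1] + os_out[, 2]) / 2,
                         (os_out[, 3] + os_out[, 4]) / 2,
                         (os_out[, 5] + os_out[, 6]) / 2)
      adv_out <- rowSums(gx * cgrad_out)
      dphi_out <- dt * (-(pmax(F_out, 0) * un_out$plus +
                            pmin(F_out, 0) * un_out$minus) +
                          p$curvature * g_edge * lap_out +
                          p$edge_attraction * adv_out)
      new_out <- phi_out + dphi_out
    } else {
      new_out <- phi_out
    }

    # non-crossing projection: interior region stays inside exterior region
    new_in <- pmax(new_in, new_out)

    band <- abs(new_in) < p$band_mm | abs(new_out) < p$band_mm
    change <- mean(abs(new_in - phi_in)[band]) +
      (if (coupled) mean(abs(new_out - phi_out)[band]) else 0)
    flips <- sum((new_in <= 0) != (phi_in <= 0)) +
      (if (coupled) sum((new_out <= 0) != (phi_out <= 0)) else 0)
    phi_in <- new_in
    phi_out <- new_out

    if (it %% p$reinit_every == 0) {
      phi_in <- signed_distance(phi_in <= 0, d, sp)
      if (coupled) phi_out <- signed_distance(phi_out <= 0, d, sp)
      phi_in <- pmax(phi_in, phi_out)
    }

    touched <- abs(phi_in - phi_out) < p$touch_mm & abs(phi_in) < 2 * h
    trace[[it]] <- data.frame(iteration = it, band_change = change,
                              flips = flips, touched = sum(touched),
                              min_separation = min(phi_in - phi_out))
    still_streak <- if (flips == 0) still_streak + 1 else 0
    # converged once the zero level sets stop moving (no voxel changes
    # region for several iterations) or the band change falls below tol
    if ((still_streak >= 5 && it %% p$reinit_every > 2) || change < p$tol) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("coupled level-set evolution hit the iteration cap (",
            p$max_iter, ") without converging", call. = FALSE)
  # final reinitialization: clean signed distances for the returned state
  # and a geometrically meaningful touched map
  phi_in <- signed_distance(phi_in <= 0, d, sp)
  phi_out <- signed_distance(phi_out <= 0, d, sp)
  phi_in <- pmax(phi_in, phi_out)
  pair$phi_in <- with_data(pair$phi_in, phi_in)
  pair$phi_out <- with_data(pair$phi_out, phi_out)
  pair$iteration <- pair$iteration + it
  pair$touched <- with_data(pair$touched, as.numeric(
    abs(phi_in - phi_out) < p$touch_mm & abs(phi_in) < 2 * h))
  pair$trace <- do.call(rbind, trace[seq_len(it)])
  pair
}

#' Intracranial mask from the evolved interior surface
#'
#' The filled region enclosed by the interior surface, reduced to its largest
#' connected component.
#'
#' @param pair Evolved `levelset_pair`.
#' @return Binary intracranial mask.
#' @export
intracranial_mask_from_surfaces <- function(pair) {
  m <- with_data(pair$phi_in, as.numeric(pair$phi_in$data <= 0), mask = TRUE)
  if (sum(m$data) == 0)
    stop("segmentation failure: empty interior region", call. = FALSE)
  mask_fill_holes(mask_largest_component(m))
}

#' Extract the intracranial CT with coupled level sets
#'
#' Convenience wrapper: initialize, evolve, and return the mask together with
#' the surface pair and the masked CT (mask times CT).
#'
#' @param ct Preprocessed CT volume.
#' @param head Binary head mask.
#' @param inner_erosion_mm Interior seed erosion, mm.
#' @param params [levelset_params()].
#' @return List with `mask`, `pair`, and `ct_masked`.
#' @export
extract_intracranial <- function(ct, head, inner_erosion_mm = 12,
                                 params = levelset_params()) {
  pair <- init_coupled_surfaces(ct, head, inner_erosion_mm)
  pair <- evolve_coupled_levelsets(ct, pair, params)
  mask <- intracranial_mask_from_surfaces(pair)
  list(mask = mask, pair = pair,
       ct_masked = with_data(ct, ct$data * mask$data))
}
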