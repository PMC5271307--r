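# ---- Intensity-based registration ---------------------------------------------
#
# Affine registration optimizes a 12-parameter transform (translation,
# rotation, log-scale, shear) over a multi-resolution pyramid with a
# deterministic Nelder-Mead search. Diffeomorphic registration is a
# symmetric, greedy, field-smoothed scheme: both images deform toward a
# common midpoint under symmetric demons-style forces with Gaussian
# regularization of the update and total fields, which yields paired
# forward/inverse displacement fields that are inverse-consistent and keep a
# positive Jacobian. Multimodal pairs are handled by re-expressing the moving
# image on the fixed image's intensity scale through a conditional-mean
# intensity remap estimated from the current joint histogram (for the MI
# metric) or by z-scoring both images (for the CC metric).

# 0-based equal-width bin index over the value range
bin_index0 <- function(v, bins, rng = range(v, na.rm = TRUE)) {
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  idx <- findInterval(v, seq(rng[1], rng[2], length.out = bins + 1),
                      rightmost.closed = TRUE)
  pmin(bins, pmax(1L, idx)) - 1L
}

# smooth MI objective for affine search: partial-volume interpolation of the
# joint histogram (trilinear weights of each sample distributed over the
# pre-binned moving image)
mi_pv <- function(fbin0, mv_binned, mv_dim, pts_vox, bins) {
  counts <- cpp_pv_jhist(mv_binned, as.integer(mv_dim), pts_vox,
                         as.integer(fbin0), as.integer(bins))
  if (sum(counts) < 64) return(-Inf)
  mutual_information(counts)
}

# foreground support of an image: deviation from the modal (background)
# intensity above 2 percent of the range, dilated by smoothing the indicator
foreground_support <- function(vals, d, bins = 64, dilate_sigma = 2) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rep(TRUE, length(vals)))
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(bins, findInterval(vals, edges, rightmost.closed = TRUE))
  mode_val <- (edges[which.max(tabulate(idx, bins))] +
                 edges[which.max(tabulate(idx, bins)) + 1]) / 2
  fg <- as.numeric(abs(vals - mode_val) > 0.02 * (rng[2] - rng[1]))
  sm <- cpp_gauss3d(fg, as.integer(d), rep(dilate_sigma, 3))
  sm > 0.01
}

reg_metric_value <- function(fv, mv, metric, bins = 32) {
  ok <- !is.na(mv) & !is.na(fv)
  if (sum(ok) < 64) return(-Inf)
  fv <- fv[ok]; mv <- mv[ok]
  if (metric == "CC") {
    if (sd(fv) == 0 || sd(mv) == 0) return(-Inf)
    return(stats::cor(fv, mv))
  }
  # MI on the paired samples
  bin_of <- function(v) {
    rng <- range(v); if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    pmin(bins, findInterval(v, seq(rng[1], rng[2], length.out = bins + 1),
                            rightmost.closed = TRUE))
  }
  counts <- matrix(tabulate(bin_of(fv) + bins * (bin_of(mv) - 1L),
                            bins * bins), bins, bins)
  mutual_information(counts)
}

# smoothed + resampled pyramid level
pyramid_level <- function(vol, factor) {
  if (factor <= 1) return(vol)
  sm <- smooth_sigma_vox(vol, rep(factor / 2, 3))
  resample_isotropic(sm, min(vol$spacing) * factor, interp = "linear")
}

affine_from_params <- function(p, center) {
  R <- rot3(3, p[6]) %*% rot3(2, p[5]) %*% rot3(1, p[4])
  Sh <- diag(3); Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  A <- R %*% Sh %*% diag(exp(p[7:9]))
  affine_transform(A, p[1:3] + center - as.numeric(A %*% center))
}

#' Default affine registration parameters
#'
#' @param bins Histogram bins for the MI metric.
#' @param levels Pyramid downsampling factors, coarse to fine.
#' @param iters Nelder-Mead iterations per level.
#' @return Named parameter list.
#' @export
affine_params <- function(bins = 32, levels = c(4, 2, 1),
                          iters = c(400, 200, 120)) {
  list(bins = bins, levels = levels, iters = iters)
}

#' Affine registration
#'
#' Finds the 12-parameter affine transform (pull-back: fixed-space points to
#' moving-space points) maximizing the chosen similarity metric, by
#' deterministic multi-resolution Nelder-Mead search on the full voxel grid.
#' The returned transform never scores below the initial one.
#'
#' @param moving,fixed Volumes with overlapping fields of view.
#' @param metric `"MI"` (multimodal) or `"CC"` (monomodal).
#' @param init Optional initial affine transform (e.g. from
#'   [rigid_initialize()]).
#' @param params [affine_params()].
#' @return An affine transform with attributes `metric` (final value) and
#'   `metric_init`.
#' @export
affine_register <- function(moving, fixed, metric = c("MI", "CC"),
                            init = NULL, params = affine_params()) {
  metric <- match.arg(metric)
  if (is.null(init)) {
    # center-of-mass translation as a robust starting point
    init <- tryCatch({
      cm <- moments_world(moving)$com
      cf <- moments_world(fixed)$com
      affine_transform(diag(3), as.numeric(cm - cf))
    }, error = function(e) identity_transform())
  }
  center <- as.numeric(voxel_to_world(fixed, matrix((vol_dim(fixed) - 1) / 2, 1)))
  p <- rep(0, 12)
  parscale <- c(rep(6, 3), rep(0.08, 3), rep(0.06, 3), rep(0.06, 3))
  fmax <- max(params$levels)
  for (li in seq_along(params$levels)) {
    f <- params$levels[li]
    ps_l <- parscale * f / fmax
    fx <- pyramid_level(fixed, f)
    mv <- pyramid_level(moving, f)
    X <- voxel_centers_world(fx)
    fvals <- as.vector(fx$data)
    fbin0 <- bin_index0(fvals, params$bins)
    mv_binned <- bin_index0(as.vector(mv$data), params$bins)
    obj <- function(q) {
      t_all <- affine_after(init, affine_from_params(q, center))
      Xm <- map_points(t_all, X)
      if (metric == "MI") {
        pts <- world_to_voxel(mv, Xm)
        val <- mi_pv(fbin0, mv_binned, vol_dim(mv), pts, params$bins)
      } else {
        mvals <- sample_at_world(mv, Xm, fill = NA_real_)
        val <- reg_metric_value(fvals, mvals, metric, params$bins)
      }
      if (!is.finite(val)) return(1e6)
      -val
    }
    res <- optim(p, obj, method = "Nelder-Mead",
                 control = list(maxit = params$iters[li],
                                parscale = ps_l, reltol = 1e-8))
    # quasi-Newton polish on the smooth PV objective (Nelder-Mead simplices
    # collapse before reaching the optimum)
    res <- tryCatch(
      optim(res$par, obj, method = "BFGS",
            control = list(maxit = 50, parscale = ps_l, reltol = 1e-10)),
      error = function(e) res)
    p <- res$par
  }
  # never return a transform scoring below the initial one (finest level)
  X <- voxel_centers_world(fixed)
  fvals <- as.vector(fixed$data)
  score <- function(t) {
    mvals <- sample_at_world(moving, map_points(t, X), fill = NA_real_)
    reg_metric_value(fvals, mvals, metric, params$bins)
  }
  t_fin <- affine_after(init, affine_from_params(p, center))
  v_fin <- score(t_fin)
  v_init <- score(init)
  if (!is.finite(v_fin) && !is.finite(v_init))
    stop("registration failure: no overlap between images", call. = FALSE)
  out <- if (v_fin >= v_init) t_fin else init
  attr(out, "metric") <- max(v_fin, v_init)
  attr(out, "metric_init") <- v_init
  out
}

# conditional intensity remap: re-express mv on fv's intensity scale via the
# per-bin median of fv (the median is robust to mixed bins: the bin holding a
# compact-support image's background also collects boundary voxels whose
# fixed-image values are nonzero, and a mean remap would lift the whole
# background, creating a constant mismatch that drives systematic drift)
intensity_remap <- function(fv, mv, bins = 32) {
  rngm <- range(mv); if (rngm[1] == rngm[2]) return(mv)
  edges <- seq(rngm[1], rngm[2], length.out = bins + 1)
  idx <- pmin(bins, findInterval(mv, edges, rightmost.closed = TRUE))
  lut <- rep(stats::median(fv), bins)
  for (b in unique(idx)) lut[b] <- stats::median(fv[idx == b])
  lut[idx]
}

#' Default diffeomorphic registration parameters
#'
#' @param levels Pyramid factors, coarse to fine.
#' @param iters Iterations per level.
#' @param sigma_update Gaussian sigma (voxels) applied to each force update
#'   (scalar, or one value per level).
#' @param sigma_total Gaussian sigma (voxels) applied to the accumulated
#'   half-fields each iteration (scalar, or one value per level).
#' @param step Step length scaling of the demons force.
#' @param max_step_vox Cap on the per-iteration displacement update, voxels.
#' @param bins Bins for MI tracing / intensity remapping.
#' @param remap_every Refresh the intensity remap every this many iterations.
#' @param gradient_floor Minimum ratio of gradient magnitude (per voxel) to
#'   intensity mismatch below which the demons force is zeroed (drift guard
#'   on flat regions).
#' @return Named parameter list.
#' @export
syn_params <- function(levels = c(4, 2, 1), iters = c(80, 50, 30),
                       sigma_update = 2.0, sigma_total = 1.0, step = 1.0,
                       max_step_vox = 0.6, bins = 32, remap_every = 5,
                       gradient_floor = 0) {
  list(levels = levels, iters = iters, sigma_update = sigma_update,
       sigma_total = sigma_total, step = step, max_step_vox = max_step_vox,
       bins = bins, remap_every = remap_every,
       gradient_floor = gradient_floor)
}

#' Symmetric diffeomorphic registration
#'
#' Greedy symmetric scheme: two half displacement fields deform the fixed and
#' moving images toward a common midpoint under shared demons-style forces;
#' the returned transform composes the inverted fixed half-field with the
#' moving half-field, giving paired forward and inverse displacement fields
#' on the fixed grid. Swapping the two input images yields (to numerical
#' tolerance) the inverse transform. Images must be affinely pre-aligned.
#'
#' @param moving,fixed Volumes; `moving` is resampled to the fixed grid if
#'   needed.
#' @param metric `"MI"` (conditional-mean intensity remap) or `"CC"`
#'   (z-scored intensities).
#' @param params [syn_params()].
#' @return An `nt_diffeo` transform with attributes `trace` (per-iteration
#'   metric) and `metric`.
#' @export
syn_register <- function(moving, fixed, metric = c("MI", "CC"),
                         params = syn_params()) {
  metric <- match.arg(metric)
  prm <- params
  if (!same_grid(moving, fixed))
    moving <- apply_transform(moving, identity_transform(), ref = fixed,
                              fill = min(moving$data))
  p_half <- NULL  # deforms the fixed image toward the midpoint
  q_half <- NULL  # deforms the moving image toward the midpoint
  prev_geom <- NULL
  trace <- list()
  for (li in seq_along(prm$levels)) {
    f <- prm$levels[li]
    fx <- pyramid_level(fixed, f)
    mv <- pyramid_level(moving, f)
    d <- vol_dim(fx)
    sp <- fx$spacing
    X <- voxel_centers_world(fx)
    if (is.null(p_half)) {
      p_half <- array(0, c(d, 3)); q_half <- array(0, c(d, 3))
    } else {
      shim <- diffeo_transform(p_half, p_half, prev_geom)
      p_half <- array(sample_field(shim, p_half, X), c(d, 3))
      q_half <- array(sample_field(shim, q_half, X), c(d, 3))
    }
    prev_geom <- fx
    fv0 <- as.vector(fx$data)
    mv0 <- as.vector(mv$data)
    if (metric == "CC") {
      fv0 <- (fv0 - mean(fv0)) / sd(fv0)
      mv0 <- (mv0 - mean(mv0)) / sd(mv0)
      fx <- with_data(fx, fv0); mv <- with_data(mv, mv0)
    }
    su_l <- if (length(prm$sigma_update) >= li) prm$sigma_update[li] else prm$sigma_update[1]
    st_l <- if (length(prm$sigma_total) >= li) prm$sigma_total[li] else prm$sigma_total[1]
    fdat <- as.double(fx$data); mdat <- as.double(mv$data)
    # forces act only on the union of the two foreground supports: over the
    # shared background, residual mismatches (remap quantization against the
    # decaying tails of smoothed compact-support images) otherwise drive a
    # small systematic drift that accumulates over iterations
    support <- foreground_support(as.vector(fx$data), d) |
      foreground_support(as.vector(mv$data), d)
    best <- list(val = -Inf, p = p_half, q = q_half)
    worse_streak <- 0
    cap_mm <- prm$max_step_vox * min(sp)
    for (it in seq_len(prm$iters[li])) {
      Pm <- matrix(p_half, ncol = 3); Qm <- matrix(q_half, ncol = 3)
      vxf <- world_to_voxel(fx, X + Pm)
      vxm <- world_to_voxel(fx, X + Qm)
      Fh <- cpp_sample3d(fdat, as.integer(d), vxf, 1L, NA_real_)
      Mh <- cpp_sample3d(mdat, as.integer(d), vxm, 1L, NA_real_)
      ok <- !is.na(Fh) & !is.na(Mh)
      Fh[!ok] <- 0; Mh[!ok] <- 0
      Mr <- if (metric == "MI") intensity_remap(Fh[ok], Mh[ok], prm$bins) else NULL
      Mh_use <- Mh
      if (!is.null(Mr)) Mh_use[ok] <- Mr
      diffv <- (Mh_use - Fh) * ok
      GF <- cpp_gradient3d(Fh, as.integer(d), as.double(sp))
      GM <- cpp_gradient3d(Mh_use, as.integer(d), as.double(sp))
      Gs <- GF + GM
      gmag2 <- rowSums(Gs^2)
      denom <- gmag2 + (diffv^2) / mean(sp)^2
      w <- ifelse(denom > 1e-12, diffv / denom, 0)
      w[!support] <- 0
      # optional drift guard: zero the force where the gradient evidence is
      # negligible relative to the intensity mismatch
      if (prm$gradient_floor > 0)
        w[gmag2 * mean(sp)^2 < prm$gradient_floor^2 * diffv^2] <- 0
      delta <- Gs * (w * prm$step)
      mx <- max(sqrt(rowSums(delta^2)))
      if (mx > cap_mm) delta <- delta * (cap_mm / mx)
      dfield <- smooth_field(array(delta, c(d, 3)), rep(su_l, 3))
      p_half <- smooth_field(p_half + 0.5 * dfield, rep(st_l, 3))
      q_half <- smooth_field(q_half - 0.5 * dfield, rep(st_l, 3))
      val <- reg_metric_value(Fh[ok], Mh[ok], metric, prm$bins)
      trace[[length(trace) + 1]] <- data.frame(level = f, iteration = it,
                                               metric = val)
      if (val > best$val) {
        best <- list(val = val, p = p_half, q = q_half)
        worse_streak <- 0
      } else {
        worse_streak <- worse_streak + 1
        if (worse_streak >= 3) break
      }
    }
    p_half <- best$p
    q_half <- best$q
  }
  geom <- fixed
  if (!identical(dim(p_half)[1:3], vol_dim(fixed))) {
    shim <- diffeo_transform(p_half, p_half, prev_geom)
    Xf <- voxel_centers_world(fixed)
    p_half <- array(sample_field(shim, p_half, Xf), c(vol_dim(fixed), 3))
    q_half <- array(sample_field(shim, q_half, Xf), c(vol_dim(fixed), 3))
  }
  inv_p <- invert_field(p_half, geom)
  inv_q <- invert_field(q_half, geom)
  X <- voxel_centers_world(geom)
  shim_q <- diffeo_transform(q_half, q_half, geom)
  shim_p <- diffeo_transform(p_half, p_half, geom)
  Yf <- X + matrix(inv_p, ncol = 3)
  u_fwd <- (Yf + sample_field(shim_q, q_half, Yf)) - X
  Ym <- X + matrix(inv_q, ncol = 3)
  u_inv <- (Ym + sample_field(shim_p, p_half, Ym)) - X
  out <- diffeo_transform(array(u_fwd, c(vol_dim(geom), 3)),
                          array(u_inv, c(vol_dim(geom), 3)), geom)
  tr <- do.call(rbind, trace)
  attr(out, "trace") <- tr
  attr(out, "metric") <- max(tr$metric)
  out
}
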