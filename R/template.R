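# ---- Groupwise unbiased template construction ---------------------------------
#
# Alternating scheme: (a) register every subject to the current template
# (affine, then symmetric diffeomorphic), (b) update the template appearance
# as the voxelwise mean of the warped subjects, (c) update the template shape
# by a small diffeomorphism toward the population average (a damped, smoothed
# negative mean of the forward displacement fields). The initial template can
# be an image in another modality (here: the MR reference), which anchors the
# result in that stereotaxic space; registration copes with the modality
# difference through MI affine alignment and intensity-remapped forces.

#' Shape update toward the population average
#'
#' Returns the damped, Gaussian-regularized negative voxelwise mean of the
#' subjects' forward displacement fields: the small diffeomorphism that moves
#' the template toward the average shape.
#'
#' @param fields List of 4D displacement arrays `c(dim, 3)` on the template
#'   grid (world mm).
#' @param step Damping fraction in (0, 1].
#' @param sigma_vox Gaussian regularization sigma, voxels.
#' @return A 4D displacement array.
#' @export
shape_update <- function(fields, step = 0.25, sigma_vox = 1) {
  if (length(fields) == 0)
    stop("no displacement fields supplied", call. = FALSE)
  acc <- fields[[1]]
  if (length(fields) > 1)
    for (i in 2:length(fields)) acc <- acc + fields[[i]]
  acc <- acc / length(fields)
  smooth_field(-step * acc, rep(sigma_vox, 3))
}

#' Groupwise unbiased template construction
#'
#' @param images List of >= 2 volumes on a common grid.
#' @param init_template Initial template guess on the same grid (may be a
#'   different modality, e.g. the MR reference template).
#' @param iterations Number of groupwise iterations (2 is typically enough
#'   once inputs are roughly aligned; 2-5 supported).
#' @param metric `"CC"` or `"MI"`: similarity used for the diffeomorphic
#'   registrations and the reported trace. Affine alignment always uses MI so
#'   a cross-modality initial template is handled transparently.
#' @param affine Parameters for [affine_register()].
#' @param syn Parameters for [syn_register()].
#' @param shape_step Damping of the shape update.
#' @param trim Optional trim fraction for a trimmed-mean appearance update.
#' @return A `template_result`: `template` (volume), `transforms` (one
#'   composite per subject), `trace` (per-iteration data frame with metric
#'   mean/sd and mean shape-update magnitude), and `fields` (final forward
#'   displacement fields).
#' @export
build_template <- function(images, init_template, iterations = 2,
                           metric = c("CC", "MI"),
                           affine = affine_params(levels = c(4, 2),
                                                  iters = c(250, 120)),
                           syn = syn_params(),
                           shape_step = 0.5, trim = 0) {
  metric <- match.arg(metric)
  if (length(images) < 2)
    stop("need at least 2 images", call. = FALSE)
  for (im in images) stop_if_grid_mismatch(im, init_template)
  template <- init_template
  n <- length(images)
  trace <- list()
  transforms <- vector("list", n)
  fields <- vector("list", n)
  for (it in seq_len(iterations)) {
    warped <- vector("list", n)
    for (s in seq_len(n)) {
      aff <- tryCatch(
        affine_register(images[[s]], template, metric = "MI", params = affine),
        error = function(e) stop("subject ", s, " registration failed: ",
                                 conditionMessage(e), call. = FALSE))
      mov_aff <- apply_transform(images[[s]], aff, ref = template,
                                 fill = min(images[[s]]$data))
      dif <- syn_register(mov_aff, template, metric = metric, params = syn)
      transforms[[s]] <- compose_transforms(list(aff, dif))
      fields[[s]] <- dif$forward
      warped[[s]] <- apply_transform(images[[s]], transforms[[s]],
                                     ref = template,
                                     fill = min(images[[s]]$data))
    }
    # appearance update: voxelwise (trimmed) mean of the warped subjects
    stack <- vapply(warped, function(w) as.vector(w$data),
                    numeric(prod(vol_dim(template))))
    mean_img <- if (trim > 0) apply(stack, 1, mean, trim = trim)
    else rowMeans(stack)
    appearance <- with_data(template, mean_img)
    # shape update: small diffeomorphism toward the average shape
    psi <- shape_update(fields, step = shape_step)
    X <- voxel_centers_world(template)
    shim <- diffeo_transform(psi, psi, template)
    Xw <- X + sample_field(shim, psi, X)
    template <- with_data(template,
                          sample_at_world(appearance, Xw,
                                          fill = min(appearance$data)))
    vals <- vapply(warped, function(w)
      reg_metric_value(as.vector(template$data), as.vector(w$data), metric),
      numeric(1))
    trace[[it]] <- data.frame(iteration = it, metric_mean = mean(vals),
                              metric_sd = sd(vals),
                              shape_update_mm = mean(sqrt(rowSums(
                                matrix(psi, ncol = 3)^2))))
  }
  structure(list(template = template, transforms = transforms,
                 trace = do.call(rbind, trace), fields = fields),
            class = "template_result")
}

#' MR intracranial template from aligned images and masks
#'
#' Voxelwise mean of the masked MR images, smoothed with a Gaussian kernel
#' (default 2 mm FWHM).
#'
#' @param mr_images List of MR volumes aligned to a common space.
#' @param icc_masks List of intracranial masks paired with the images.
#' @param fwhm_mm Smoothing kernel FWHM, mm.
#' @return The intracranial template volume.
#' @export
build_mr_intracranial_template <- function(mr_images, icc_masks, fwhm_mm = 2) {
  if (length(mr_images) != length(icc_masks))
    stop("images and masks must pair up", call. = FALSE)
  if (length(mr_images) == 0) stop("no images supplied", call. = FALSE)
  for (i in seq_along(mr_images))
    stop_if_grid_mismatch(mr_images[[i]], icc_masks[[i]])
  acc <- as.vector(mr_images[[1]]$data) * as.vector(icc_masks[[1]]$data)
  if (length(mr_images) > 1)
    for (i in 2:length(mr_images))
      acc <- acc + as.vector(mr_images[[i]]$data) * as.vector(icc_masks[[i]]$data)
  gaussian_smooth(with_data(mr_images[[1]], acc / length(mr_images)), fwhm_mm)
}
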