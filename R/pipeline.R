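# ---- End-to-end pipeline -------------------------------------------------------
#
# Orchestrates the full flow: CT preprocessing, coupled level-set
# intracranial extraction, two-step registration to the MR reference
# (intracranial affine + symmetric diffeomorphic, then whole-head MI affine),
# groupwise CT template construction initialized with the MR template, and
# MI/CC validation scenarios.

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable list. The
#' defaults mirror the reference protocol: 0.47 mm isotropic re-slicing, the
#' three-segment CT intensity transform switched on, 2 groupwise iterations,
#' 2 mm FWHM template smoothing before MI evaluation, base-2 logs.
#'
#' @param iso_spacing Isotropic target spacing in mm, or `NULL` to keep the
#'   native grid.
#' @param intensity_transform Apply the CT intensity transform.
#' @param open_radius_mm,close_radius_mm Head-mask morphology radii, mm.
#' @param inner_erosion_mm Interior level-set seed erosion, mm.
#' @param icc_smooth_fwhm Gaussian FWHM (mm) applied to the masked
#'   intracranial CT before registering it to the MR intracranial template,
#'   matching that template's own smoothing so the two boundary profiles
#'   agree.
#' @param levelset [levelset_params()].
#' @param affine [affine_params()].
#' @param syn [syn_params()].
#' @param template_iterations Groupwise iterations.
#' @param build_metric Similarity for template building.
#' @param eval_fwhm_mm Template smoothing before MI evaluation, mm.
#' @param bins Histogram bins for evaluation MI.
#' @param log_base Logarithm base for entropy/MI.
#' @param seed Seed for phantom generation helpers.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(iso_spacing = 0.47, intensity_transform = TRUE,
                            open_radius_mm = NULL, close_radius_mm = NULL,
                            inner_erosion_mm = 12, icc_smooth_fwhm = 2,
                            levelset = levelset_params(),
                            affine = affine_params(), syn = syn_params(),
                            template_iterations = 2,
                            build_metric = "CC", eval_fwhm_mm = 2, bins = 64,
                            log_base = 2, seed = 1L) {
  structure(list(iso_spacing = iso_spacing,
                 intensity_transform = intensity_transform,
                 open_radius_mm = open_radius_mm,
                 close_radius_mm = close_radius_mm,
                 inner_erosion_mm = inner_erosion_mm,
                 icc_smooth_fwhm = icc_smooth_fwhm, levelset = levelset,
                 affine = affine, syn = syn,
                 template_iterations = template_iterations,
                 build_metric = build_metric, eval_fwhm_mm = eval_fwhm_mm,
                 bins = bins, log_base = log_base, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' YAML round trip: `read_config(write_config(cfg, path))` equals `cfg`.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

# preprocess one CT: head mask, background cleaning, optional intensity
# transform, optional isotropic re-slicing
preprocess_ct <- function(ct, config) {
  if (!is.null(config$iso_spacing) &&
      max(abs(ct$spacing - config$iso_spacing)) > 1e-9)
    ct <- resample_isotropic(ct, config$iso_spacing)
  open_r <- config$open_radius_mm
  close_r <- config$close_radius_mm
  if (is.null(open_r)) open_r <- min(ct$spacing)
  if (is.null(close_r)) close_r <- 2 * min(ct$spacing)
  head <- extract_head_mask(ct, open_r, close_r)
  ct_clean <- clean_background(ct, head)
  ct_pp <- if (isTRUE(config$intensity_transform))
    transform_ct_intensity(ct_clean) else ct_clean
  list(ct_pp = ct_pp, ct_clean = ct_clean, head = head)
}

# bone threshold on the working intensity scale
bone_threshold_for <- function(config) {
  thr <- config$levelset$bone_threshold
  if (isTRUE(config$intensity_transform)) transform_ct_intensity(thr) else thr
}

#' Two-step registration of a raw CT to the MR reference
#'
#' Step 0: preprocessing (head mask, background cleaning, intensity
#' transform, optional isotropic re-slicing) and programmatic rigid
#' initialization to the MR template space. Step 1: coupled level-set
#' intracranial extraction, then affine (MI) + symmetric diffeomorphic (MI)
#' registration of the intracranial CT to the MR intracranial template; the
#' resulting deformation is applied to the whole preprocessed CT, yielding
#' CT'. Step 2: whole-head affine registration of CT' to the MR template
#' under MI, yielding CT''.
#'
#' @param ct_raw Raw CT volume (HU).
#' @param mr_template MR reference template volume.
#' @param mr_icc_template MR intracranial template volume (same grid).
#' @param config [pipeline_config()].
#' @return List: `ct_pp` (CT'' on the MR grid), `transform` (composite from
#'   the preprocessed CT to the MR space), and `intermediates` (head mask,
#'   intracranial mask, CT', metric values).
#' @export
two_step_register <- function(ct_raw, mr_template, mr_icc_template, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pp <- stage("preprocess", preprocess_ct(ct_raw, config))
  rigid <- stage("rigid-init", rigid_initialize(pp$ct_pp, mr_template))
  ct_r <- apply_transform(pp$ct_pp, rigid, ref = mr_template,
                          fill = min(pp$ct_pp$data))
  head_r <- apply_transform(pp$head, rigid, interp = "nearest",
                            ref = mr_template)
  lsp <- config$levelset
  lsp$bone_threshold <- bone_threshold_for(config)
  icc <- stage("intracranial",
               extract_intracranial(ct_r, head_r, config$inner_erosion_mm, lsp))
  sm_fwhm <- if (is.null(config$icc_smooth_fwhm)) 2 else config$icc_smooth_fwhm
  ct_icc <- gaussian_smooth(with_data(ct_r, ct_r$data * icc$mask$data),
                            sm_fwhm)
  aff1 <- stage("intracranial-affine",
                affine_register(ct_icc, mr_icc_template, metric = "MI",
                                params = config$affine))
  ct_icc_aff <- apply_transform(ct_icc, aff1, ref = mr_icc_template, fill = 0)
  dif <- stage("intracranial-syn",
               syn_register(ct_icc_aff, mr_icc_template, metric = "MI",
                            params = config$syn))
  t_intra <- compose_transforms(list(aff1, dif))
  ct_prime <- apply_transform(ct_r, t_intra, ref = mr_template,
                              fill = min(ct_r$data))
  aff2 <- stage("whole-head-affine",
                affine_register(ct_prime, mr_template, metric = "MI",
                                params = config$affine))
  ct_pp2 <- apply_transform(ct_prime, aff2, ref = mr_template,
                            fill = min(ct_prime$data))
  total <- compose_transforms(list(rigid, aff1, dif, aff2))
  list(ct_pp = ct_pp2,
       transform = total,
       intermediates = list(head_mask = head_r, icc_mask = icc$mask,
                            ct_preprocessed = ct_r, ct_prime = ct_prime,
                            levelset_trace = icc$pair$trace,
                            mi_intracranial = attr(dif, "metric"),
                            mi_whole_head = attr(aff2, "metric")))
}

#' Run the full template-construction pipeline
#'
#' Two-step registration of every subject CT into the MR template space, then
#' groupwise unbiased template construction on the CT'' set with the MR
#' template as the initial guess. The template is returned on the working
#' intensity scale and, when the intensity transform is active, also in
#' Hounsfield units via the exact inverse transform.
#'
#' @param ct_list List of raw CT volumes (HU).
#' @param mr_template,mr_icc_template MR reference and intracranial template.
#' @param config [pipeline_config()].
#' @return List: `template` (working scale), `template_hu` (HU scale or
#'   `NULL`), `subjects` (CT'' volumes), `transforms`, `build`
#'   (the `template_result`).
#' @export
run_template_pipeline <- function(ct_list, mr_template, mr_icc_template,
                                  config = pipeline_config()) {
  if (length(ct_list) < 2)
    stop("need at least 2 CT inputs", call. = FALSE)
  regs <- vector("list", length(ct_list))
  for (i in seq_along(ct_list)) {
    regs[[i]] <- tryCatch(
      two_step_register(ct_list[[i]], mr_template, mr_icc_template, config),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  subjects <- lapply(regs, `[[`, "ct_pp")
  build <- build_template(subjects, mr_template,
                          iterations = config$template_iterations,
                          metric = config$build_metric,
                          affine = config$affine, syn = config$syn)
  template_hu <- if (isTRUE(config$intensity_transform))
    inverse_ct_intensity(with_data(build$template,
                                   pmax(0, as.vector(build$template$data))))
  else NULL
  list(template = build$template, template_hu = template_hu,
       subjects = subjects,
       transforms = lapply(regs, `[[`, "transform"),
       build = build)
}

# intra-modality normalization of an image to the template: affine (CC) then
# symmetric diffeomorphic (CC)
normalize_to_template <- function(img, template, config) {
  aff <- affine_register(img, template, metric = "CC", params = config$affine)
  img_aff <- apply_transform(img, aff, ref = template, fill = min(img$data))
  dif <- syn_register(img_aff, template, metric = "CC", params = config$syn)
  apply_transform(img, compose_transforms(list(aff, dif)), ref = template,
                  fill = min(img$data))
}

#' Evaluate a CT template by spatial normalization of test images
#'
#' Each test image is normalized to the template (affine then diffeomorphic,
#' both under CC, as in intra-modality normalization), and its MI with the
#' template --- smoothed by a Gaussian kernel (default 2 mm FWHM) --- is
#' reported, along with the MI before normalization.
#'
#' @param test_images List of >= 1 CT volumes on the template intensity scale.
#' @param ct_template Template volume.
#' @param config [pipeline_config()].
#' @return An `evaluation_report`: data frame `per_image` (mi_before,
#'   mi_after), `mi_mean`, `mi_sd`, `n`, and the list of normalized images.
#' @export
evaluate_template <- function(test_images, ct_template,
                              config = pipeline_config()) {
  tmpl_s <- gaussian_smooth(ct_template, config$eval_fwhm_mm)
  n <- length(test_images)
  mi_before <- numeric(n); mi_after <- numeric(n)
  normalized <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      norm_i <- normalize_to_template(test_images[[i]], ct_template, config)
      list(norm = norm_i,
           before = mutual_information(test_images[[i]], tmpl_s,
                                       bins = config$bins,
                                       base = config$log_base),
           after = mutual_information(norm_i, tmpl_s, bins = config$bins,
                                      base = config$log_base))
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE
      mi_before[i] <- NA_real_; mi_after[i] <- NA_real_
    } else {
      normalized[[i]] <- res$norm
      mi_before[i] <- res$before
      mi_after[i] <- res$after
    }
  }
  structure(list(per_image = data.frame(image = seq_len(n),
                                        mi_before = mi_before,
                                        mi_after = mi_after,
                                        failed = failed),
                 mi_mean = mean(mi_after[!failed]),
                 mi_sd = sd(mi_after[!failed]),
                 n = n, normalized = normalized),
            class = "evaluation_report")
}

#' Pairwise similarity of normalized images
#'
#' Normalizes every image to the template and computes the cross-correlation
#' of every unordered pair of normalized images: n images yield n(n-1)/2
#' pairs.
#'
#' @param test_images List of >= 2 CT volumes.
#' @param ct_template Template volume.
#' @param config [pipeline_config()].
#' @return List: `pairs` data frame (i, j, cc_before, cc_after), `cc_mean`,
#'   `cc_sd`, `n_pairs`.
#' @export
pairwise_normalization_similarity <- function(test_images, ct_template,
                                              config = pipeline_config()) {
  n <- length(test_images)
  if (n < 2) stop("need at least 2 images", call. = FALSE)
  normalized <- lapply(test_images, normalize_to_template, ct_template, config)
  pairs <- utils::combn(n, 2)
  cc_b <- numeric(ncol(pairs)); cc_a <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cc_b[k] <- cross_correlation(test_images[[i]], test_images[[j]])
    cc_a[k] <- cross_correlation(normalized[[i]], normalized[[j]])
  }
  list(pairs = data.frame(i = pairs[1, ], j = pairs[2, ],
                          cc_before = cc_b, cc_after = cc_a),
       cc_mean = mean(cc_a), cc_sd = sd(cc_a), n_pairs = ncol(pairs))
}
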