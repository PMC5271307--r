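# ---- Binary morphology (Euclidean, via exact distance transforms) -------------

mask_edt <- function(mask_data, dims, spacing) {
  cpp_edt3d(as.integer(mask_data != 0), as.integer(dims), as.double(spacing))
}

#' Morphological operations on binary masks
#'
#' Euclidean-ball structuring elements realized through exact distance
#' transforms, so anisotropic voxel grids are handled in mm.
#'
#' @param mask Binary mask.
#' @param radius_mm Ball radius in mm.
#' @return Binary mask.
#' @name morphology
NULL

#' @rdname morphology
#' @export
mask_dilate <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  d <- mask_edt(mask$data, vol_dim(mask), mask$spacing)
  with_data(mask, as.numeric(d <= radius_mm), mask = TRUE)
}

#' @rdname morphology
#' @export
mask_erode <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  d <- mask_edt(1 - mask$data, vol_dim(mask), mask$spacing)
  with_data(mask, as.numeric(d > radius_mm), mask = TRUE)
}

#' @rdname morphology
#' @export
mask_open <- function(mask, radius_mm) mask_dilate(mask_erode(mask, radius_mm), radius_mm)

#' @rdname morphology
#' @export
mask_close <- function(mask, radius_mm) mask_erode(mask_dilate(mask, radius_mm), radius_mm)

#' Fill interior cavities of a binary mask
#'
#' Background voxels not 6-connected to the grid boundary are added to the
#' mask.
#'
#' @param mask Binary mask.
#' @return Hole-free binary mask.
#' @export
mask_fill_holes <- function(mask) {
  d <- vol_dim(mask)
  bg <- array(mask$data == 0, d)
  lab <- array(cpp_label3d(as.integer(bg), as.integer(d), 6L), d)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels != 0]
  keep_bg <- array(lab %in% border_labels, d)
  with_data(mask, as.numeric(mask$data == 1 | (bg & !keep_bg)), mask = TRUE)
}

#' Largest connected component of a mask
#' @param mask Binary mask.
#' @param connectivity 6 or 26.
#' @return Binary mask keeping only the largest component.
#' @export
mask_largest_component <- function(mask, connectivity = 26) {
  d <- vol_dim(mask)
  lab <- cpp_label3d(as.integer(mask$data != 0), as.integer(d),
                     as.integer(connectivity))
  if (all(lab == 0))
    stop("segmentation failure: empty mask", call. = FALSE)
  tab <- tabulate(lab)
  with_data(mask, as.numeric(lab == which.max(tab)), mask = TRUE)
}

#' Count connected components of a mask
#' @param mask Binary mask.
#' @param connectivity 6 or 26.
#' @return Integer component count.
#' @export
mask_n_components <- function(mask, connectivity = 26) {
  lab <- cpp_label3d(as.integer(mask$data != 0), as.integer(vol_dim(mask)),
                     as.integer(connectivity))
  max(lab)
}

# ---- Otsu thresholding ---------------------------------------------------------

#' Otsu's threshold
#'
#' Maximizes the between-class variance of the intensity histogram. Ties are
#' broken toward the smallest threshold. The returned value is translation
#' equivariant: shifting all intensities by c shifts the threshold by c.
#'
#' @param vol Volume (or numeric vector of intensities).
#' @param mask Optional binary mask restricting the histogram.
#' @param nbins Number of histogram bins.
#' @return The threshold intensity; voxels strictly above it form the
#'   foreground class.
#' @export
otsu_threshold <- function(vol, mask = NULL, nbins = 256) {
  x <- if (is_volume(vol)) as.vector(vol$data) else as.numeric(vol)
  if (!is.null(mask)) {
    if (is_volume(vol)) stop_if_grid_mismatch(vol, mask)
    x <- x[as.vector(mask$data) == 1]
  }
  if (length(unique(x)) < 2L)
    stop("degenerate input: fewer than 2 distinct values", call. = FALSE)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(nbins, findInterval(x, edges, rightmost.closed = TRUE)),
                nbins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)   # which.max takes the first (smallest) maximizer
  edges[k + 1]
}

# ---- Head mask and background cleaning ----------------------------------------

#' Extract the head mask from a CT volume
#'
#' Otsu thresholding followed by binary opening, selection of the largest
#' connected component, closing, and hole filling. Nuisance structures
#' disconnected from the head (pillow, pacifier, the artificial rim) are
#' discarded with the non-head components.
#'
#' @param ct CT volume in HU with an air background.
#' @param open_radius_mm,close_radius_mm Structuring-element radii.
#' @return Binary head mask: one connected component, hole-free.
#' @export
extract_head_mask <- function(ct, open_radius_mm = 1 * min(ct$spacing),
                              close_radius_mm = 2 * min(ct$spacing)) {
  # values below the physical CT floor (-1024) are reconstruction artifacts
  # (the -3000 rim); clamp them to air so they cannot dominate the histogram
  clamped <- pmax(as.vector(ct$data), -1000)
  thr <- otsu_threshold(clamped)
  fg <- with_data(ct, as.numeric(clamped > thr), mask = TRUE)
  if (sum(fg$data) == 0)
    stop("segmentation failure: no above-threshold voxels", call. = FALSE)
  m <- mask_open(fg, open_radius_mm)
  if (sum(m$data) == 0)
    stop("segmentation failure: opening removed all foreground", call. = FALSE)
  m <- mask_largest_component(m)
  m <- mask_close(m, close_radius_mm)
  mask_fill_holes(m)
}

#' Assign air to everything outside the head
#'
#' Every voxel outside the head mask is set to exactly -1000 HU; voxels inside
#' are untouched. This also removes the artificial rim (intensity well below
#' -1024), which always lies outside the head mask. Idempotent.
#'
#' @param ct CT volume (HU).
#' @param head Binary head mask on the same grid.
#' @param air_hu Background value, default -1000.
#' @return Cleaned CT volume.
#' @export
clean_background <- function(ct, head, air_hu = -1000) {
  stop_if_grid_mismatch(ct, head)
  out <- as.vector(ct$data)
  out[as.vector(head$data) == 0] <- air_hu
  with_data(ct, out)
}

# ---- CT intensity transform ----------------------------------------------------

#' Three-segment CT intensity transform
#'
#' Invertible piecewise-linear mapping that brings the CT intensity range
#' close to the MR range and expands the soft-tissue dynamic range:
#' \itemize{
#'   \item -1000 to -100 HU map linearly to 0-900,
#'   \item -99 to 100 HU map linearly to 901-3100,
#'   \item above 100 HU, intensities map to I + 3000.
#' }
#' Inputs below -1000 HU (e.g. the artificial rim, if it survived
#' preprocessing) are clamped to -1000 with a message. The map is strictly
#' increasing, hence invertible via [inverse_ct_intensity()].
#'
#' @param v Numeric vector/scalar of HU values, or a volume.
#' @return Transformed values (same shape as the input).
#' @export
transform_ct_intensity <- function(v) {
  if (is_volume(v)) return(with_data(v, transform_ct_intensity(as.vector(v$data))))
  if (anyNA(v)) stop("NaN/NA in intensity input", call. = FALSE)
  if (any(v < -1000)) {
    message("clamping ", sum(v < -1000), " value(s) below -1000 HU")
    v <- pmax(v, -1000)
  }
  out <- numeric(length(v))
  lo <- v <= -99
  mid <- v > -99 & v <= 100
  hi <- v > 100
  out[lo] <- v[lo] + 1000
  out[mid] <- 901 + (v[mid] + 99) * (2199 / 199)
  out[hi] <- v[hi] + 3000
  out
}

#' Inverse of the CT intensity transform
#'
#' @param v Transformed intensities (>= 0), numeric or volume.
#' @return HU values, such that
#'   `inverse_ct_intensity(transform_ct_intensity(x)) == x` for `x >= -1000`.
#' @export
inverse_ct_intensity <- function(v) {
  if (is_volume(v)) return(with_data(v, inverse_ct_intensity(as.vector(v$data))))
  if (anyNA(v)) stop("NaN/NA in intensity input", call. = FALSE)
  if (any(v < 0)) stop("input outside the transform's range [0, Inf)",
                       call. = FALSE)
  out <- numeric(length(v))
  lo <- v <= 901
  mid <- v > 901 & v <= 3100
  hi <- v > 3100
  out[lo] <- v[lo] - 1000
  out[mid] <- -99 + (v[mid] - 901) * (199 / 2199)
  out[hi] <- v[hi] - 3000
  out
}
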