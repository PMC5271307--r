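#' @useDynLib neotemplate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd optim setNames
NULL

# ---- Volume class ------------------------------------------------------------
#
# A volume is a 3D scalar array plus explicit grid geometry. World coordinates
# follow the RAS convention; voxel indices are 0-based and the center of voxel
# (i,j,k) sits at origin + direction %*% (spacing * c(i,j,k)).

#' Create a volume
#'
#' Bundles a 3D scalar array with its grid geometry (voxel spacing in mm,
#' world origin, and an orthonormal direction matrix mapping voxel axes to
#' world RAS axes).
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, world position (mm) of the center of voxel
#'   (0,0,0).
#' @param direction 3x3 orthonormal matrix (voxel axes to world axes).
#' @return An object of class `nt_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be strictly positive", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal", call. = FALSE)
  if (anyNA(data))
    stop("volume data contains NA/NaN", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "nt_volume")
}

#' Create a binary mask volume
#'
#' A mask is a volume whose voxels are exactly 0 or 1.
#'
#' @inheritParams volume
#' @return An object of class `c("nt_mask", "nt_volume")`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  v <- volume(data * 1.0, spacing, origin, direction)
  if (!all(v$data %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  class(v) <- c("nt_mask", class(v))
  v
}

#' @export
print.nt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %dx%dx%d, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Is an object a volume?
#' @param x Object.
#' @return Logical.
#' @export
is_volume <- function(x) inherits(x, "nt_volume")

vol_dim <- function(vol) dim(vol$data)

# keep geometry, replace data
with_data <- function(vol, data, mask = FALSE) {
  data <- array(data, dim = vol_dim(vol))
  if (mask) binary_mask(data, vol$spacing, vol$origin, vol$direction)
  else volume(data, vol$spacing, vol$origin, vol$direction)
}

#' Convert a volume to a binary mask
#' @param vol Volume with values in \{0,1\}.
#' @return Binary mask on the same grid.
#' @export
as_mask <- function(vol) {
  binary_mask(vol$data, vol$spacing, vol$origin, vol$direction)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("volumes are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

# n x 3 matrix of world coordinates of all voxel centers, in R array order
voxel_centers_world <- function(vol) {
  d <- vol_dim(vol)
  ix <- rep.int(seq_len(d[1]) - 1L, times = d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  idx <- cbind(ix, iy, iz)
  M <- vol$direction %*% diag(vol$spacing)
  sweep(idx %*% t(M), 2, vol$origin, "+")
}

# world (n x 3) -> continuous 0-based voxel coordinates of `vol`
world_to_voxel <- function(vol, X) {
  Minv <- diag(1 / vol$spacing) %*% t(vol$direction)
  sweep(X, 2, vol$origin, "-") %*% t(Minv)
}

voxel_to_world <- function(vol, idx) {
  M <- vol$direction %*% diag(vol$spacing)
  sweep(idx %*% t(M), 2, vol$origin, "+")
}

# sample vol at world points (n x 3); interp "linear" or "nearest"
sample_at_world <- function(vol, X, interp = "linear", fill = 0) {
  vx <- world_to_voxel(vol, X)
  ord <- if (interp == "nearest") 0L else 1L
  cpp_sample3d(as.double(vol$data), as.integer(vol_dim(vol)), vx, ord,
               as.double(fill))
}

# ---- NIfTI I/O ---------------------------------------------------------------

#' Read a 3D volume from a NIfTI file
#'
#' The NIfTI xform (sform/qform) is decomposed into spacing, origin, and an
#' orthonormal direction matrix; intensities are returned unchanged.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A volume.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop("expected a 3D image, got ", length(dim(a)), " dimensions",
         call. = FALSE)
  a <- array(as.double(a), dim = dim(a))   # drop NIfTI attributes
  M <- RNifti::xform(img)
  A <- M[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2, spacing, "/")
  volume(a, spacing = spacing, origin = M[1:3, 4], direction = direction)
}

#' Read a binary mask from a NIfTI file
#' @inheritParams read_volume
#' @return A binary mask.
#' @export
read_mask <- function(path) as_mask(read_volume(path))

#' Write a volume to a NIfTI file
#'
#' Data are stored as float64 so write/read round trips preserve full
#' precision; grid geometry goes into both sform and qform.
#'
#' @param vol Volume.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("directory does not exist: ", dir, call. = FALSE)
  if (file.access(dir, 2) != 0)
    stop("directory not writable: ", dir, call. = FALSE)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  M <- diag(4)
  M[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  M[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(M, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(M, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# ---- Resampling and smoothing ------------------------------------------------

#' Resample a volume to isotropic spacing
#'
#' The output grid shares the input's origin and direction; the number of
#' voxels along each axis is chosen so the world-space extent is preserved to
#' within one voxel.
#'
#' @param vol Volume.
#' @param target_spacing Positive scalar, mm.
#' @param interp `"linear"` (intensity images) or `"nearest"` (masks).
#' @return Resampled volume (a mask input with nearest interpolation stays a
#'   mask).
#' @export
resample_isotropic <- function(vol, target_spacing,
                               interp = if (inherits(vol, "nt_mask")) "nearest" else "linear") {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be a positive scalar", call. = FALSE)
  d <- vol_dim(vol)
  nd <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  out <- volume(array(0, nd), spacing = rep(target_spacing, 3),
                origin = vol$origin, direction = vol$direction)
  X <- voxel_centers_world(out)
  vals <- sample_at_world(vol, X, interp = interp,
                          fill = if (interp == "nearest") 0 else min(vol$data))
  out$data <- array(vals, nd)
  if (inherits(vol, "nt_mask") && interp == "nearest") out <- as_mask(out)
  out
}

#' Gaussian smoothing of a volume
#'
#' The kernel width is given as full width at half maximum in mm and converted
#' to a per-axis sigma in voxels via sigma = FWHM / (2 sqrt(2 ln 2)). Edges are
#' handled by replication, which keeps total intensity conserved away from the
#' boundary without darkening it.
#'
#' @param vol Volume.
#' @param fwhm_mm Non-negative kernel FWHM in mm; 0 returns the input.
#' @return Smoothed volume.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm < 0)
    stop("fwhm_mm must be a non-negative scalar", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  smooth_sigma_vox(vol, sigma_mm / vol$spacing)
}

# smoothing by explicit per-axis sigma in voxels (internal)
smooth_sigma_vox <- function(vol, sigma_vox) {
  if (all(sigma_vox <= 0)) return(vol)
  sm <- cpp_gauss3d(as.double(vol$data), as.integer(vol_dim(vol)),
                    as.double(sigma_vox))
  volume(array(sm, vol_dim(vol)), vol$spacing, vol$origin, vol$direction)
}

#' FWHM to Gaussian sigma conversion
#' @param fwhm Full width at half maximum.
#' @return The corresponding Gaussian standard deviation.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# ---- Rigid initialization ----------------------------------------------------

# intensity-weighted center of mass and principal axes, in world coordinates;
# weights are the foreground excess over an Otsu split so a large static
# background (air) cannot dominate the moments
moments_world <- function(vol) {
  v <- pmax(as.vector(vol$data), -1000)   # sub-air artifact floor
  thr <- tryCatch(otsu_threshold(v), error = function(e) min(v))
  w <- pmax(v - thr, 0)
  if (sum(w) <= 0) w <- v - min(v)
  tw <- sum(w)
  if (tw <= 0) stop("constant image: cannot compute moments", call. = FALSE)
  X <- voxel_centers_world(vol)
  com <- colSums(X * w) / tw
  Xc <- sweep(X, 2, com, "-")
  C <- crossprod(Xc * w, Xc) / tw
  e <- eigen(C, symmetric = TRUE)
  list(com = com, axes = e$vectors, lambda = e$values)
}

#' Rigid initialization by centers of mass and principal axes
#'
#' Computes a rigid (rotation + translation) transform that approximately
#' aligns `moving` onto `fixed` from intensity moments, serving as the
#' "almost aligned" starting point for intensity-based registration. The
#' returned transform maps fixed-space world points to moving-space world
#' points (the resampling convention used throughout).
#'
#' @param moving,fixed Volumes with non-constant intensity.
#' @return An affine transform (rigid).
#' @export
rigid_initialize <- function(moving, fixed) {
  if (diff(range(moving$data)) == 0 || diff(range(fixed$data)) == 0)
    stop("degenerate input: constant image", call. = FALSE)
  mm <- moments_world(moving)
  mf <- moments_world(fixed)
  Vm <- mm$axes
  Vf <- mf$axes
  # resolve eigenvector sign ambiguity: make each moving axis agree with the
  # corresponding fixed axis (valid in the "almost aligned" regime)
  for (k in 1:3) if (sum(Vm[, k] * Vf[, k]) < 0) Vm[, k] <- -Vm[, k]
  R <- Vm %*% t(Vf)
  if (det(R) < 0) { Vm[, 3] <- -Vm[, 3]; R <- Vm %*% t(Vf) }
  affine_transform(matrix = R, translation = as.numeric(mm$com - R %*% mf$com))
}
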