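# ---- Spatial transforms ------------------------------------------------------
#
# All transforms use the resampling (pull-back) convention: a transform maps
# world points of the FIXED image domain to world points of the MOVING image
# domain, so warping an image means sampling the moving image at mapped fixed
# voxel centers. Image-level composition "apply t1 then t2" therefore
# corresponds to point-level application of t2 first, then t1.

#' Create an affine transform
#'
#' A 12-parameter spatial map `x -> matrix %*% x + translation` from
#' fixed-space to moving-space world coordinates.
#'
#' @param matrix 3x3 matrix (rotation, scale, shear) with positive determinant.
#' @param translation Length-3 translation, mm.
#' @return An `nt_affine` object.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (det(matrix) <= 0)
    stop("affine matrix must have positive determinant", call. = FALSE)
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "nt_affine")
}

#' Identity transform
#' @return An identity affine transform.
#' @export
identity_transform <- function() affine_transform()

#' Invert an affine transform
#' @param t Affine transform.
#' @return The inverse affine transform.
#' @export
invert_affine <- function(t) {
  Ai <- solve(t$matrix)
  affine_transform(Ai, -as.numeric(Ai %*% t$translation))
}

# point-level composition: returns transform u with u(x) = a(b(x))
affine_after <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix,
                   as.numeric(a$matrix %*% b$translation) + a$translation)
}

#' Create a diffeomorphic transform from displacement fields
#'
#' Forward and inverse dense displacement fields (mm, world frame) sampled on
#' a reference grid. The forward field maps fixed-space points to
#' moving-space points: `x -> x + forward(x)`.
#'
#' @param forward,inverse 4D arrays `c(dim, 3)` of world-frame displacements
#'   in mm on the reference grid.
#' @param geometry A volume (or volume-like list) supplying the reference grid
#'   geometry.
#' @return An `nt_diffeo` object.
#' @export
diffeo_transform <- function(forward, inverse, geometry) {
  d <- dim(forward)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement fields must be c(dim, 3) arrays", call. = FALSE)
  if (!identical(dim(inverse), d))
    stop("forward and inverse fields must share dimensions", call. = FALSE)
  structure(list(forward = forward, inverse = inverse,
                 spacing = geometry$spacing, origin = geometry$origin,
                 direction = geometry$direction, dim = d[1:3]),
            class = "nt_diffeo")
}

field_component_volume <- function(t, field, k) {
  volume(array(field[, , , k], t$dim), t$spacing, t$origin, t$direction)
}

# sample a displacement field (stored on t's grid) at world points X;
# outside the grid the displacement is 0
sample_field <- function(t, field, X) {
  u <- base::matrix(0, nrow(X), 3)
  geom <- list(spacing = t$spacing, origin = t$origin, direction = t$direction)
  vx <- world_to_voxel(structure(geom, class = "nt_volume"), X)
  for (k in 1:3)
    u[, k] <- cpp_sample3d(as.double(field[, , , k]), as.integer(t$dim), vx,
                           1L, 0)
  u
}

#' Map world points through a transform
#'
#' @param t An affine, diffeomorphic, or composite transform.
#' @param X n x 3 matrix of world points (fixed space).
#' @param inverse Use the inverse mapping.
#' @return n x 3 matrix of mapped world points (moving space).
#' @export
map_points <- function(t, X, inverse = FALSE) {
  UseMethod("map_points")
}

#' @export
map_points.nt_affine <- function(t, X, inverse = FALSE) {
  tt <- if (inverse) invert_affine(t) else t
  sweep(X %*% t(tt$matrix), 2, tt$translation, "+")
}

#' @export
map_points.nt_diffeo <- function(t, X, inverse = FALSE) {
  f <- if (inverse) t$inverse else t$forward
  X + sample_field(t, f, X)
}

#' @export
map_points.nt_composite <- function(t, X, inverse = FALSE) {
  # components are stored in image application order (moving -> fixed);
  # the pull-back applies the last image operation's map first
  comps <- if (inverse) t$transforms else rev(t$transforms)
  for (tc in comps) X <- map_points(tc, X, inverse = inverse)
  X
}

#' Compose transforms
#'
#' Components are listed in image application order: `ts[[1]]` is applied to
#' the moving image first. Applying the composite equals applying each
#' component in sequence.
#'
#' @param ts List of transforms (affine, diffeo, or composite; composites are
#'   flattened). An empty list yields the identity transform.
#' @return An `nt_composite` transform (or the identity affine).
#' @export
compose_transforms <- function(ts) {
  flat <- list()
  for (t in ts) {
    if (inherits(t, "nt_composite")) flat <- c(flat, t$transforms)
    else if (inherits(t, "nt_affine") || inherits(t, "nt_diffeo"))
      flat <- c(flat, list(t))
    else stop("not a transform: ", paste(class(t), collapse = "/"),
              call. = FALSE)
  }
  if (length(flat) == 0L) return(identity_transform())
  if (length(flat) == 1L) return(flat[[1]])
  structure(list(transforms = flat), class = "nt_composite")
}

#' Apply a transform to a volume
#'
#' Resamples `vol` (the moving image) onto the grid of `ref` through the
#' transform: output voxel x takes the value of `vol` at the mapped point.
#'
#' @param vol Moving volume.
#' @param t Transform (affine, diffeo, or composite).
#' @param interp `"linear"` or `"nearest"`.
#' @param fill Intensity assigned outside the moving image's field of view.
#' @param ref Volume defining the output grid; defaults to the transform's
#'   reference grid for diffeomorphic transforms, else to `vol`.
#' @return Warped volume on the grid of `ref`.
#' @export
apply_transform <- function(vol, t, interp = "linear", fill = 0, ref = NULL) {
  if (is.null(ref)) {
    ref <- if (inherits(t, "nt_diffeo"))
      structure(list(data = array(0, t$dim), spacing = t$spacing,
                     origin = t$origin, direction = t$direction),
                class = "nt_volume")
    else vol
  }
  X <- voxel_centers_world(ref)
  Xm <- map_points(t, X)
  vals <- sample_at_world(vol, Xm, interp = interp, fill = fill)
  out <- volume(array(vals, vol_dim(ref)), ref$spacing, ref$origin,
                ref$direction)
  if (inherits(vol, "nt_mask") && interp == "nearest") out <- as_mask(out)
  out
}

# ---- Field utilities ----------------------------------------------------------

# numerically invert a displacement field (voxelwise fixed point iteration);
# field and output are on grid `geom`, displacements in world mm
invert_field <- function(field, geom, iters = 25) {
  d <- dim(field)[1:3]
  X <- voxel_centers_world(geom)
  t0 <- diffeo_transform(field, field, geom)  # sampling shim
  V <- base::matrix(0, nrow(X), 3)
  for (i in seq_len(iters)) {
    V_new <- -sample_field(t0, field, X + V)
    if (max(abs(V_new - V)) < 1e-4) { V <- V_new; break }
    V <- V_new
  }
  array(V, c(d, 3))
}

#' Jacobian determinant of a deformation
#'
#' Finite-difference Jacobian determinant of the map `x + u(x)` for a dense
#' displacement field.
#'
#' @param field 4D displacement array `c(dim, 3)` in world mm.
#' @param geometry Volume-like object carrying the grid geometry.
#' @return 3D array of Jacobian determinants.
#' @export
jacobian_determinant <- function(field, geometry) {
  d <- dim(field)[1:3]
  sp <- geometry$spacing
  Dir <- geometry$direction
  # gradient of each world displacement component along voxel axes (per mm)
  J <- vector("list", 3)
  for (k in 1:3)
    J[[k]] <- cpp_gradient3d(as.double(field[, , , k]), as.integer(d),
                             as.double(sp))
  # du_world/dx_world = (du/d(voxel mm)) %*% t(Dir); det(I + that)
  n <- prod(d)
  det_v <- numeric(n)
  g1 <- J[[1]] %*% t(Dir); g2 <- J[[2]] %*% t(Dir); g3 <- J[[3]] %*% t(Dir)
  a11 <- 1 + g1[, 1]; a12 <- g1[, 2]; a13 <- g1[, 3]
  a21 <- g2[, 1]; a22 <- 1 + g2[, 2]; a23 <- g2[, 3]
  a31 <- g3[, 1]; a32 <- g3[, 2]; a33 <- 1 + g3[, 3]
  det_v <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  array(det_v, d)
}

# smooth each component of a displacement field (sigma in voxels);
# zeropad = TRUE tapers the field to zero at the grid boundary
smooth_field <- function(field, sigma_vox, zeropad = FALSE) {
  if (all(sigma_vox <= 0)) return(field)
  d <- dim(field)
  out <- field
  for (k in 1:3)
    out[, , , k] <- array(cpp_gauss3d(as.double(field[, , , k]),
                                      as.integer(d[1:3]),
                                      as.double(sigma_vox),
                                      as.integer(zeropad)), d[1:3])
  out
}

# ---- Serialization -------------------------------------------------------------

#' Write a transform to disk
#'
#' Affines are stored as a 4x4 matrix text file; diffeomorphic transforms as a
#' pair of displacement-field NIfTI files plus a JSON sidecar; composites as a
#' JSON manifest referencing components in application order.
#'
#' @param t Transform.
#' @param path Output path prefix (extension added per component).
#' @return Invisibly, the manifest/main file path.
#' @export
write_transform <- function(t, path) {
  UseMethod("write_transform")
}

#' @export
write_transform.nt_affine <- function(t, path) {
  f <- paste0(path, ".affine.txt")
  M <- rbind(cbind(t$matrix, t$translation), c(0, 0, 0, 1))
  utils::write.table(format(M, digits = 17), f, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(f)
}

#' @export
write_transform.nt_diffeo <- function(t, path) {
  geom <- structure(list(data = array(0, t$dim), spacing = t$spacing,
                         origin = t$origin, direction = t$direction),
                    class = "nt_volume")
  for (tag in c("forward", "inverse")) {
    fld <- t[[tag]]
    for (k in 1:3)
      write_volume(with_data(geom, fld[, , , k]),
                   sprintf("%s.%s.%d.nii.gz", path, tag, k))
  }
  f <- paste0(path, ".diffeo.json")
  jsonlite::write_json(list(type = "diffeo", dim = t$dim, spacing = t$spacing,
                            origin = t$origin,
                            direction = as.vector(t$direction)),
                       f, auto_unbox = TRUE, digits = NA)
  invisible(f)
}

#' @export
write_transform.nt_composite <- function(t, path) {
  comp <- character(length(t$transforms))
  for (i in seq_along(t$transforms))
    comp[i] <- write_transform(t$transforms[[i]], sprintf("%s.%02d", path, i))
  f <- paste0(path, ".composite.json")
  jsonlite::write_json(list(type = "composite", components = comp), f,
                       auto_unbox = TRUE)
  invisible(f)
}

#' Read a transform written by [write_transform()]
#' @param path Path returned by [write_transform()].
#' @return The transform.
#' @export
read_transform <- function(path) {
  if (grepl("\\.affine\\.txt$", path)) {
    M <- as.matrix(utils::read.table(path))
    return(affine_transform(M[1:3, 1:3], M[1:3, 4]))
  }
  if (grepl("\\.diffeo\\.json$", path)) {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    base <- sub("\\.diffeo\\.json$", "", path)
    d <- as.integer(meta$dim)
    fwd <- array(0, c(d, 3)); inv <- array(0, c(d, 3))
    geom <- NULL
    for (k in 1:3) {
      v <- read_volume(sprintf("%s.forward.%d.nii.gz", base, k))
      fwd[, , , k] <- v$data
      inv[, , , k] <- read_volume(sprintf("%s.inverse.%d.nii.gz", base, k))$data
      geom <- v
    }
    return(diffeo_transform(fwd, inv, geom))
  }
  if (grepl("\\.composite\\.json$", path)) {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(compose_transforms(lapply(meta$components, read_transform)))
  }
  stop("unrecognized transform file: ", path, call. = FALSE)
}
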