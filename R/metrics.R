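# ---- Similarity and overlap measures ------------------------------------------

#' Joint intensity histogram of two volumes
#'
#' @param x,y Volumes on the same grid.
#' @param bins Number of bins per image (>= 2).
#' @param mask Optional binary mask restricting the paired voxels.
#' @return An `nt_jhist`: `counts` (bins x bins), `edges_x`, `edges_y`, `n`.
#' @export
joint_histogram <- function(x, y, bins = 64, mask = NULL) {
  stop_if_grid_mismatch(x, y)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  xv <- as.vector(x$data)
  yv <- as.vector(y$data)
  if (!is.null(mask)) {
    stop_if_grid_mismatch(x, mask)
    sel <- as.vector(mask$data) == 1
    xv <- xv[sel]; yv <- yv[sel]
  }
  bin_of <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
    list(idx = pmin(bins, findInterval(v, edges, rightmost.closed = TRUE)),
         edges = edges)
  }
  bx <- bin_of(xv)
  by <- bin_of(yv)
  counts <- matrix(tabulate(bx$idx + bins * (by$idx - 1L), bins * bins),
                   bins, bins)
  structure(list(counts = counts, edges_x = bx$edges, edges_y = by$edges,
                 n = length(xv)),
            class = "nt_jhist")
}

#' Shannon entropy of an intensity distribution
#'
#' For a volume, the entropy of its intensity histogram; for a numeric
#' vector, the entropy of those histogram counts (or probabilities) directly.
#' Zero-mass bins contribute nothing (0 log 0 := 0).
#'
#' @param x Volume, or numeric vector of histogram counts/probabilities.
#' @param bins Number of bins (volumes only).
#' @param base Logarithm base; 2 gives bits.
#' @param mask Optional mask (volumes only).
#' @return Entropy, >= 0; zero iff one bin carries all mass.
#' @export
entropy <- function(x, bins = 64, base = 2, mask = NULL) {
  if (is_volume(x)) {
    h <- joint_histogram(x, x, bins = bins, mask = mask)
    p <- rowSums(h$counts)
  } else {
    p <- as.numeric(x)
  }
  if (length(p) == 0 || sum(p) <= 0)
    stop("empty histogram", call. = FALSE)
  if (any(p < 0)) stop("negative histogram mass", call. = FALSE)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Mutual information between two volumes
#'
#' Histogram estimate of `I(X,Y) = sum p(x,y) log[ p(x,y) / (p(x) p(y)) ]`.
#' Symmetric, non-negative, bounded by the marginal entropies, and equal to
#' the entropy of one image when the two are identical; zero-count cells are
#' skipped (0 log 0 := 0).
#'
#' @param x,y Volumes on the same grid, or `x` may be an `nt_jhist` (or a
#'   bins x bins count/probability matrix) with `y` omitted.
#' @param bins Bin count per image.
#' @param mask Optional binary mask.
#' @param base Logarithm base; 2 gives bits.
#' @return Mutual information value.
#' @export
mutual_information <- function(x, y = NULL, bins = 64, mask = NULL, base = 2) {
  counts <- if (inherits(x, "nt_jhist")) x$counts
  else if (is.matrix(x) && is.null(y)) x
  else joint_histogram(x, y, bins = bins, mask = mask)$counts
  p <- counts / sum(counts)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pv <- p[nz]
  sum(pv * log(pv / (px[nz[, 1]] * py[nz[, 2]]))) / log(base)
}

#' Cross-correlation (Pearson) between two volumes
#'
#' @param x,y Volumes on the same grid, non-constant within the mask.
#' @param mask Optional binary mask.
#' @return Correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(x, y, mask = NULL) {
  stop_if_grid_mismatch(x, y)
  xv <- as.vector(x$data); yv <- as.vector(y$data)
  if (!is.null(mask)) {
    stop_if_grid_mismatch(x, mask)
    sel <- as.vector(mask$data) == 1
    xv <- xv[sel]; yv <- yv[sel]
  }
  if (sd(xv) == 0 || sd(yv) == 0)
    stop("degenerate input: constant image", call. = FALSE)
  as.numeric(stats::cor(xv, yv))
}

#' Dice overlap of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`. Two empty masks count as perfectly overlapping
#' (Dice 1), with a message.
#'
#' @param a,b Binary masks on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a$data * b$data) / (na + nb)
}
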