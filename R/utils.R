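# Shared array/grid helpers. Axis order is (x, y[, z]) with dim 1 = x;
# coordinates are 0-indexed voxel centers (array [i,j] <-> coord (i-1, j-1)).

#' @noRd
grid_dim <- function(grid_shape) length(grid_shape)

#' Coordinates of all voxel centers, one row per voxel in array order.
#' @noRd
grid_coords <- function(grid_shape) {
  axes <- lapply(grid_shape, function(n) seq_len(n) - 1)
  m <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Tensor-times-matrix along one axis: contracts dim `axis` of `arr`
#' (length n) with an m x n matrix, returning an array with that axis
#' replaced by length m.
#' @noRd
ttm <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  a <- matrix(a, nrow = d[axis])
  out <- M %*% a
  dim(out) <- c(nrow(M), d[-axis])
  aperm(out, order(perm))
}

#' Row-normalized 1-D Gaussian filtering matrix (n x n).
#' @noRd
gaussian_filter_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

#' Separable Gaussian smoothing of a scalar array (any dimension).
#' @noRd
smooth_gaussian <- function(arr, sigma) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  a <- array(arr, dim = d)
  for (ax in seq_along(d)) {
    a <- ttm(a, gaussian_filter_matrix(d[ax], sigma), ax)
  }
  a
}

#' Multilinear interpolation of a scalar grid at arbitrary points.
#'
#' `points` is an n x d matrix of 0-indexed coordinates; out-of-grid
#' positions are clamped to the border (nearest-border extension).
#' @noRd
interp_image <- function(img, points) {
  d <- dim(img)
  nd <- length(d)
  points <- matrix(points, ncol = nd)
  # clamp into [0, n-1]
  for (ax in seq_len(nd)) {
    points[, ax] <- pmin(pmax(points[, ax], 0), d[ax] - 1)
  }
  lo <- floor(points)
  frac <- points - lo
  lo1 <- lo + 1 # 1-based lower corner
  n <- nrow(points)
  out <- numeric(n)
  strides <- cumprod(c(1, d[-nd]))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    w <- rep(1, n)
    lin <- rep(1, n)
    for (ax in seq_len(nd)) {
      iax <- pmin(lo1[, ax] + off[ax], d[ax])
      lin <- lin + (iax - 1) * strides[ax]
      w <- w * if (off[ax] == 1) frac[, ax] else (1 - frac[, ax])
    }
    out <- out + w * img[lin]
  }
  out
}

#' Multilinear interpolation of a multi-channel field (channels last) at
#' points; returns an n x C matrix.
#' @noRd
interp_field <- function(field, points) {
  d <- dim(field)
  nc <- d[length(d)]
  gs <- d[-length(d)]
  points <- matrix(points, ncol = length(gs))
  out <- matrix(0, nrow(points), nc)
  idx <- c(lapply(gs, seq_len), list(1))
  for (ch in seq_len(nc)) {
    idx[[length(idx)]] <- ch
    out[, ch] <- interp_image(array(do.call(`[`, c(list(field), idx)), gs), points)
  }
  out
}

#' Evaluate a deterministic expression under a temporary RNG seed.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

#' Derive a bounded child seed from a parent seed and stream index.
#' @noRd
child_seed <- function(seed, index) {
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647
}

#' @noRd
stopifnot_grid_match <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("inputs must share the same grid shape", call. = FALSE)
  }
}
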