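# Conversions between the landmark, label, one-hot and surface
# representations that the different model families consume, plus the
# image-wise distances (ASSD, L1) used by every evaluation metric.

coord_cols <- function(d) c("x", "y", "z")[seq_len(d)]

#' Flatten a landmark table into a corresponded shape vector
#'
#' Rows are ordered by `structure` then `point_index`; coordinates are
#' interleaved per point (x1, y1\[, z1\], x2, ...), giving the
#' `d * m`-dimensional shape vector that the statistical models operate on.
#' The row layout is kept as an attribute so the vector can be unflattened.
#'
#' @param landmarks tibble with columns `structure`, `point_index`, `x`,
#'   `y` and optionally `z`.
#' @return numeric vector of length `d * m` with attributes `layout`
#'   (structure/point_index tibble) and `d`.
#' @export
landmarks_flatten <- function(landmarks) {
  d <- if ("z" %in% names(landmarks)) 3L else 2L
  landmarks <- dplyr::arrange(landmarks, .data$structure, .data$point_index)
  m <- as.matrix(landmarks[, coord_cols(d)])
  v <- as.vector(t(m))
  attr(v, "layout") <- landmarks[, c("structure", "point_index")]
  attr(v, "d") <- d
  v
}

#' Rebuild a landmark table from a flattened shape vector
#'
#' @param shape numeric vector as produced by [landmarks_flatten()], or any
#'   vector of the same length if `layout` is supplied.
#' @param layout optional structure/point_index tibble; defaults to the
#'   vector's own `layout` attribute.
#' @return landmark tibble.
#' @export
landmarks_unflatten <- function(shape, layout = attr(shape, "layout")) {
  if (is.null(layout)) stop("no landmark layout available", call. = FALSE)
  m <- nrow(layout)
  d <- length(shape) / m
  if (d != round(d)) stop("shape length is not a multiple of the landmark count", call. = FALSE)
  coords <- matrix(as.numeric(shape), nrow = m, ncol = d, byrow = TRUE)
  colnames(coords) <- coord_cols(d)
  dplyr::bind_cols(tibble::as_tibble(layout), tibble::as_tibble(coords))
}

#' @noRd
shape_points <- function(shape) {
  d <- attr(shape, "d")
  if (is.null(d)) stop("shape vector carries no dimension attribute", call. = FALSE)
  matrix(as.numeric(shape), ncol = d, byrow = TRUE)
}

# ---- rasterization ---------------------------------------------------------

rasterize_polygon_2d <- function(poly, grid_shape) {
  stopifnot(nrow(poly) >= 3)
  pts <- grid_coords(grid_shape)
  # restrict to the polygon's bounding box for speed
  inbox <- pts[, 1] >= floor(min(poly[, 1])) & pts[, 1] <= ceiling(max(poly[, 1])) &
    pts[, 2] >= floor(min(poly[, 2])) & pts[, 2] <= ceiling(max(poly[, 2]))
  mask <- logical(nrow(pts))
  if (any(inbox)) {
    mask[inbox] <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                                pts[inbox, , drop = FALSE])
  }
  array(mask, dim = grid_shape)
}

# Star-shaped 3D rasterization: a voxel belongs to the structure when its
# distance from the landmark centroid is below the radius obtained by
# inverse-angular-distance interpolation of the landmark radii on the unit
# sphere. Our own construction; the source data's contouring scheme is not
# reproduced (see vignette).
rasterize_star_3d <- function(pts3, grid_shape) {
  stopifnot(nrow(pts3) >= 4)
  ctr <- colMeans(pts3)
  rel <- sweep(pts3, 2, ctr)
  rad <- sqrt(rowSums(rel^2))
  dirs <- rel / pmax(rad, 1e-12)
  vox <- grid_coords(grid_shape)
  vrel <- sweep(vox, 2, ctr)
  vdist <- sqrt(rowSums(vrel^2))
  vdir <- vrel / pmax(vdist, 1e-12)
  cosang <- pmin(pmax(vdir %*% t(dirs), -1), 1)
  ang <- acos(cosang)
  w <- 1 / (ang^2 + 1e-6)
  rhat <- as.vector((w %*% rad) / rowSums(w))
  array(vdist <= rhat, dim = grid_shape)
}

#' Rasterize corresponded landmarks into a multi-structure label image
#'
#' Each structure's landmark loop is filled (2D: exact point-in-polygon on
#' voxel centers; 3D: star-shaped radial interpolation about the structure
#' centroid). Structures are painted in the order given by
#' `structure_order`, so on overlapping voxels the later-listed structure
#' wins.
#'
#' @param landmarks landmark tibble or flattened shape vector (with layout).
#' @param grid_shape integer extent per axis.
#' @param structure_order paint order; defaults to increasing structure id.
#' @return integer label array (`0` = background) of dim `grid_shape`.
#' @export
landmarks_to_label <- function(landmarks, grid_shape, structure_order = NULL) {
  if (!is.data.frame(landmarks)) landmarks <- landmarks_unflatten(landmarks)
  d <- if ("z" %in% names(landmarks)) 3L else 2L
  stopifnot(length(grid_shape) == d)
  if (is.null(structure_order)) structure_order <- sort(unique(landmarks$structure))
  lab <- array(0L, dim = grid_shape)
  for (s in structure_order) {
    pts <- dplyr::arrange(landmarks[landmarks$structure == s, ], .data$point_index)
    if (nrow(pts) < d + 1) {
      stop("structure ", s, " is degenerate (fewer than ", d + 1, " landmarks)", call. = FALSE)
    }
    p <- as.matrix(pts[, coord_cols(d)])
    mask <- if (d == 2) rasterize_polygon_2d(p, grid_shape) else rasterize_star_3d(p, grid_shape)
    lab[mask] <- as.integer(s)
  }
  lab
}

# ---- one-hot ---------------------------------------------------------------

#' One-hot encode a label image
#'
#' @param label integer label array with labels in `0..L`.
#' @param L largest label; defaults to `max(label)`.
#' @return array of dim `c(dim(label), L + 1)`; channel `l + 1` carries the
#'   indicator of label `l`, so per-voxel channel sums are exactly 1.
#' @export
label_to_onehot <- function(label, L = max(label)) {
  if (any(label > L)) stop("labels exceed L", call. = FALSE)
  d <- dim(label)
  oh <- array(0, dim = c(d, L + 1))
  n <- prod(d)
  oh[seq_len(n) + n * as.vector(label)] <- 1
  oh
}

#' Collapse a (soft) one-hot image to labels by per-voxel argmax
#'
#' Ties are broken toward the lowest channel index (so a 0.5/0.5 voxel
#' becomes background). Per-voxel channel sums must be 1 within `1e-3`.
#'
#' @param oh one-hot array, channels last.
#' @return integer label array.
#' @export
onehot_to_label <- function(oh) {
  d <- dim(oh)
  nc <- d[length(d)]
  gs <- d[-length(d)]
  m <- matrix(oh, ncol = nc)
  sums <- rowSums(m)
  if (max(abs(sums - 1)) > 1e-3) {
    stop("one-hot channel sums deviate from 1 by more than 1e-3", call. = FALSE)
  }
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), dim = gs)
}

# ---- surfaces and distances ------------------------------------------------

#' Extract the voxel-center surface of one structure
#'
#' A structure voxel is a surface voxel when at least one face-adjacent
#' neighbour (4-connectivity in 2D, 6 in 3D) carries a different label or
#' lies outside the grid.
#'
#' @param label integer label array.
#' @param structure structure id.
#' @param spacing physical units per voxel (scalar or per-axis).
#' @return matrix of surface point coordinates (physical units); zero rows
#'   if the structure is absent.
#' @export
extract_surface <- function(label, structure, spacing = 1) {
  d <- dim(label)
  nd <- length(d)
  spacing <- rep(spacing, length.out = nd)
  mask <- label == structure
  if (!any(mask)) return(matrix(numeric(0), 0, nd))
  border <- array(FALSE, dim = d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    idx_lo <- lapply(d, seq_len); idx_lo[[ax]] <- c(1L, seq_len(n - 1))
    idx_hi <- lapply(d, seq_len); idx_hi[[ax]] <- c(seq_len(n - 1) + 1L, n)
    nb_lo <- do.call(`[`, c(list(label), idx_lo))
    nb_hi <- do.call(`[`, c(list(label), idx_hi))
    border <- border | (nb_lo != label) | (nb_hi != label)
    # grid-edge voxels are surface voxels
    edge <- lapply(d, seq_len)
    edge[[ax]] <- c(1L, n)
    e <- array(FALSE, dim = d)
    e <- do.call(`[<-`, c(list(e), edge, list(TRUE)))
    border <- border | e
  }
  coords <- grid_coords(d)[as.vector(mask & border), , drop = FALSE]
  sweep(coords, 2, spacing, `*`)
}

min_cross_dist <- function(A, B) {
  # for each row of A, distance to the nearest row of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Average symmetric surface distance between two label images
#'
#' For each structure, surface point sets are extracted from both images and
#' the mean of all bidirectional nearest-neighbour distances is taken; the
#' result is averaged over structures. A structure absent from both images
#' is excluded with a warning; a structure absent from exactly one image
#' contributes the grid diagonal as a finite penalty (the omission itself is
#' tracked by [missing_structures()]).
#'
#' @param a,b integer label arrays on the same grid.
#' @param structures structure ids to evaluate; defaults to all non-zero
#'   labels present in either image.
#' @param spacing physical units per voxel.
#' @return non-negative scalar; 0 iff all compared surfaces coincide.
#' @export
assd <- function(a, b, structures = NULL, spacing = 1) {
  stopifnot_grid_match(a, b)
  if (is.null(structures)) {
    structures <- sort(setdiff(unique(c(as.vector(a), as.vector(b))), 0))
  }
  nd <- length(dim(a))
  spacing <- rep(spacing, length.out = nd)
  diag_len <- sqrt(sum(((dim(a) - 1) * spacing)^2))
  vals <- numeric(0)
  for (s in structures) {
    Sa <- extract_surface(a, s, spacing)
    Sb <- extract_surface(b, s, spacing)
    if (nrow(Sa) == 0 && nrow(Sb) == 0) {
      warning("structure ", s, " absent in both images; excluded from ASSD")
      next
    }
    if (nrow(Sa) == 0 || nrow(Sb) == 0) {
      vals <- c(vals, diag_len)
      next
    }
    dab <- min_cross_dist(Sa, Sb)
    dba <- min_cross_dist(Sb, Sa)
    vals <- c(vals, (sum(dab) + sum(dba)) / (length(dab) + length(dba)))
  }
  if (length(vals) == 0) stop("no structure present in either image", call. = FALSE)
  mean(vals)
}

#' Mean absolute intensity difference between two images
#'
#' @param a,b numeric arrays on the same grid.
#' @return non-negative scalar.
#' @export
l1_distance <- function(a, b) {
  stopifnot_grid_match(a, b)
  mean(abs(a - b))
}

#' Fraction of expected structures missing from a label image
#'
#' @param label integer label array.
#' @param expected_structures structure ids that should be present.
#' @return fraction in \[0, 1\].
#' @export
missing_structures <- function(label, expected_structures) {
  stopifnot(length(expected_structures) >= 1)
  present <- expected_structures %in% unique(as.vector(label))
  mean(!present)
}
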