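# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with the package: plain
# double loops and textbook formulas only.

# ray-casting point-in-polygon (even-odd rule), one point at a time
oracle_in_polygon <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, grid_shape) {
  out <- array(FALSE, grid_shape)
  for (ix in seq_len(grid_shape[1])) {
    for (iy in seq_len(grid_shape[2])) {
      out[ix, iy] <- oracle_in_polygon(poly, ix - 1, iy - 1)
    }
  }
  out
}

# all-pairs O(n^2) average symmetric surface distance for one structure set
oracle_assd_points <- function(A, B) {
  dmin_a <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    dmin_a[i] <- min(sqrt(rowSums((B - matrix(A[i, ], nrow(B), ncol(B),
                                              byrow = TRUE))^2)))
  }
  dmin_b <- numeric(nrow(B))
  for (i in seq_len(nrow(B))) {
    dmin_b[i] <- min(sqrt(rowSums((A - matrix(B[i, ], nrow(A), ncol(A),
                                              byrow = TRUE))^2)))
  }
  (sum(dmin_a) + sum(dmin_b)) / (length(dmin_a) + length(dmin_b))
}

# boundary voxels of one structure by explicit neighbour loops
oracle_surface <- function(label, s) {
  d <- dim(label)
  pts <- NULL
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      if (label[ix, iy] != s) next
      edge <- ix == 1 || ix == d[1] || iy == 1 || iy == d[2]
      if (!edge) {
        edge <- label[ix - 1, iy] != s || label[ix + 1, iy] != s ||
          label[ix, iy - 1] != s || label[ix, iy + 1] != s
      }
      if (edge) pts <- rbind(pts, c(ix - 1, iy - 1))
    }
  }
  pts
}

oracle_assd_labels <- function(a, b, structures) {
  vals <- numeric(0)
  diag_len <- sqrt(sum((dim(a) - 1)^2))
  for (s in structures) {
    A <- oracle_surface(a, s)
    B <- oracle_surface(b, s)
    if (is.null(A) && is.null(B)) next
    if (is.null(A) || is.null(B)) {
      vals <- c(vals, diag_len)
      next
    }
    vals <- c(vals, oracle_assd_points(A, B))
  }
  mean(vals)
}

# Kolmogorov-Smirnov sup over every breakpoint, by direct counting
oracle_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  best <- 0
  for (x in xs) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    best <- max(best, abs(fa - fb))
  }
  best
}

# weighted generalized Dice loss by direct summation
oracle_gdl <- function(pred, target) {
  L <- dim(pred)[length(dim(pred))]
  pm <- matrix(pred, ncol = L)
  tm <- matrix(target, ncol = L)
  w <- num <- den <- numeric(L)
  for (l in seq_len(L)) {
    vol <- sum(tm[, l])
    w[l] <- 1 / max(vol, 1)^2
    num[l] <- sum(pm[, l] * tm[, l])
    den[l] <- sum(pm[, l]) + sum(tm[, l])
  }
  1 - 2 * sum(w * num) / sum(w * den)
}

# diffusion + L1 displacement regularizer by explicit loops (2D field)
oracle_displacement_reg <- function(field) {
  gs <- dim(field)[1:2]
  d <- dim(field)[3]
  sq <- 0; ndiff <- 0
  for (ch in seq_len(d)) {
    for (ix in seq_len(gs[1] - 1)) for (iy in seq_len(gs[2])) {
      sq <- sq + (field[ix + 1, iy, ch] - field[ix, iy, ch])^2
      ndiff <- ndiff + 1
    }
    for (ix in seq_len(gs[1])) for (iy in seq_len(gs[2] - 1)) {
      sq <- sq + (field[ix, iy + 1, ch] - field[ix, iy, ch])^2
      ndiff <- ndiff + 1
    }
  }
  10 * sq / ndiff + 10 * sum(abs(field)) / prod(gs)
}

# random little label images for property tests
random_label_image <- function(gs = c(16, 16), L = 2) {
  lab <- array(0L, gs)
  for (s in seq_len(L)) {
    cx <- runif(1, 0.2 * gs[1], 0.8 * gs[1])
    cy <- runif(1, 0.2 * gs[2], 0.8 * gs[2])
    r <- runif(1, 1.2, max(2, gs[1] / 4))
    for (ix in seq_len(gs[1])) for (iy in seq_len(gs[2])) {
      if ((ix - 1 - cx)^2 + (iy - 1 - cy)^2 <= r^2) lab[ix, iy] <- s
    }
  }
  lab
}
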