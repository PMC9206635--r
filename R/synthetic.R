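# Ground-truth deformation bases and population sampling. Instances are
# produced by displacing the template landmarks with a linear combination of
# smooth zero-mean modes (coefficients drawn Normal(0, sigma_j^2)),
# rasterizing the displaced landmarks, and warping the template appearance
# (plus a per-instance smooth intensity offset) with the same deformation.

flatten_modes <- function(basis) {
  vapply(basis$modes, as.vector, numeric(prod(basis$grid_shape) * basis$d))
}

#' Build a basis of smooth ground-truth deformation modes
#'
#' Each mode is a Gaussian-smoothed random displacement field, made zero
#' mean per channel, orthogonalized (Gram-Schmidt) against the previous
#' modes, and scaled to unit root-mean-square displacement magnitude, so
#' that a coefficient of `sigma` produces typical displacements of about
#' `sigma` voxels.
#'
#' @param template a [build_template()] result.
#' @param k number of modes (>= 1).
#' @param smoothness Gaussian kernel width (voxels) of the mode fields;
#'   small values give localized variation, large values global modes.
#'   Default `max(grid_shape) / 8`.
#' @param amplitudes per-mode standard deviations `sigma_j` (voxels);
#'   default `2 * 0.8^(j-1)`.
#' @param seed integer seed; fixed seed gives bit-identical bases.
#' @return object of class `deformation_basis` with fields `modes` (list of
#'   `c(grid_shape, d)` arrays), `amplitudes`, `smoothness`, `seed`.
#' @export
build_deformation_basis <- function(template, k, smoothness = NULL,
                                    amplitudes = NULL, seed = 1) {
  stopifnot(inherits(template, "shape_template"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  gs <- template$grid_shape
  d <- length(gs)
  if (is.null(smoothness)) smoothness <- max(gs) / 8
  dof <- prod(gs) * d - d # zero-mean constraint per channel
  if (k > dof) stop("k exceeds the grid's degrees of freedom", call. = FALSE)
  if (is.null(amplitudes)) amplitudes <- 2 * 0.8^(seq_len(k) - 1)
  if (length(amplitudes) != k || any(amplitudes <= 0)) {
    stop("amplitudes must have length k and be positive", call. = FALSE)
  }

  with_seed(seed, {
    kept <- list()
    flat_kept <- NULL
    nvox <- prod(gs)
    while (length(kept) < k) {
      f <- array(rnorm(nvox * d), dim = c(gs, d))
      for (ch in seq_len(d)) {
        idx <- slice.index(f, d + 1) == ch
        sm <- smooth_gaussian(array(f[idx], gs), smoothness)
        f[idx] <- sm - mean(sm)
      }
      v <- as.vector(f)
      if (!is.null(flat_kept)) v <- v - flat_kept %*% crossprod(flat_kept, v)
      nrm <- sqrt(sum(v^2))
      if (nrm < 1e-8) next # degenerate draw, resample
      v <- v / nrm
      flat_kept <- cbind(flat_kept, v)
      # unit RMS displacement magnitude
      kept[[length(kept) + 1]] <- array(v * sqrt(nvox), dim = c(gs, d))
    }
    structure(
      list(modes = kept, amplitudes = amplitudes, smoothness = smoothness,
           seed = seed, grid_shape = gs, d = d, k = k),
      class = "deformation_basis"
    )
  })
}

compose_field <- function(basis, coefficients) {
  stopifnot(length(coefficients) == basis$k)
  f <- array(0, dim = c(basis$grid_shape, basis$d))
  for (j in seq_len(basis$k)) f <- f + coefficients[j] * basis$modes[[j]]
  f
}

smooth_noise_field <- function(grid_shape, sigma) {
  a <- smooth_gaussian(array(rnorm(prod(grid_shape)), grid_shape), sigma)
  s <- stats::sd(as.vector(a))
  if (s < 1e-12) array(0, grid_shape) else (a - mean(a)) / s
}

#' Draw one instance from a template and deformation basis
#'
#' The deformation `phi = sum_j c_j mode_j` displaces the template landmarks
#' (evaluated at the landmark positions); the label image is the
#' rasterization of the displaced landmarks; the appearance is the template
#' plus a smooth per-instance intensity offset, carried along the same
#' deformation (the appearance grid is resampled through the numerically
#' inverted field so that labels and appearance stay aligned).
#'
#' With all coefficients and `offset_scale` zero the instance equals the
#' template exactly.
#'
#' @param template a [build_template()] result.
#' @param basis a [build_deformation_basis()] result.
#' @param coefficients numeric vector of length `k`.
#' @param offset_scale standard deviation of the smooth intensity offset
#'   (intensity units; 0 disables it).
#' @param seed optional seed for the offset draw; when `NULL` the current
#'   RNG state is used (as inside [sample_population()]).
#' @return object of class `shape_instance` with `landmarks`, `label`,
#'   `appearance`, `true_coefficients`, `true_intensity_offset`.
#' @export
sample_instance <- function(template, basis, coefficients, offset_scale = 0,
                            seed = NULL) {
  stopifnot(inherits(template, "shape_template"), inherits(basis, "deformation_basis"))
  if (length(coefficients) != basis$k) {
    stop("coefficients must have length k", call. = FALSE)
  }
  if (any(!is.finite(coefficients))) stop("coefficients must be finite", call. = FALSE)
  run <- function() {
    gs <- template$grid_shape
    d <- length(gs)
    phi <- compose_field(basis, coefficients)
    pts <- as.matrix(template$landmarks[, coord_cols(d)])
    disp <- interp_field(phi, pts)
    new_pts <- pts + disp
    if (any(new_pts < 0) || any(sweep(new_pts, 2, gs - 1) > 0)) {
      stop(structure(
        class = c("shapearena_instance_rejected", "error", "condition"),
        list(message = "displaced landmark outside grid; reduce amplitudes",
             call = NULL)
      ))
    }
    lm <- template$landmarks
    lm[, coord_cols(d)] <- tibble::as_tibble(as.data.frame(new_pts))
    label <- landmarks_to_label(lm, gs, template$structure_order)
    if (offset_scale > 0) {
      offset <- offset_scale * smooth_noise_field(gs, basis$smoothness / 2)
    } else {
      offset <- array(0, gs)
    }
    src <- pmin(pmax(template$appearance + offset, 0), 1)
    if (all(coefficients == 0)) {
      appearance <- src
    } else {
      appearance <- warp(src, invert_field(phi), mode = "intensity")
    }
    structure(
      list(landmarks = lm, label = label, appearance = appearance,
           true_coefficients = coefficients, true_intensity_offset = offset),
      class = "shape_instance"
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Draw a full population with train/validation/test splits
#'
#' Coefficients are drawn `c_j ~ Normal(0, sigma_j^2)` with the basis
#' amplitudes as `sigma`. An instance whose displaced landmarks leave the
#' grid is rejected and redrawn (at most 100 attempts). Split sizes use
#' floor for train, then validation, remainder to test; instances are
#' assigned to splits in index order (they are exchangeable by
#' construction).
#'
#' @param template,basis as in [sample_instance()].
#' @param n population size (>= 3).
#' @param offset_scale per-instance intensity-offset scale (default 0.05).
#' @param split_fractions train/validation/test fractions summing to 1.
#' @param seed integer seed; fixed seed gives a bit-identical population.
#' @param representations which per-instance representations to realise;
#'   dropping `"label"`/`"appearance"` skips rasterization/warping when only
#'   landmarks are needed.
#' @return object of class `shape_population`.
#' @export
sample_population <- function(template, basis, n, offset_scale = 0.05,
                              split_fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                              seed = 1,
                              representations = c("landmarks", "label", "appearance")) {
  stopifnot(n >= 3)
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  light <- !("label" %in% representations) && !("appearance" %in% representations)
  with_seed(seed, {
    instances <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(100)) {
        coeff <- rnorm(basis$k, 0, basis$amplitudes)
        res <- tryCatch(
          if (light) {
            light_instance(template, basis, coeff)
          } else {
            sample_instance(template, basis, coeff, offset_scale)
          },
          shapearena_instance_rejected = function(e) NULL
        )
        if (!is.null(res)) { instances[[i]] <- res; ok <- TRUE; break }
      }
      if (!ok) {
        stop("instance rejected 100 times; use smaller deformation amplitudes",
             call. = FALSE)
      }
    }
    n_train <- floor(split_fractions[[1]] * n)
    n_val <- floor(split_fractions[[2]] * n)
    split <- list(train = seq_len(n_train),
                  validation = seq_len(n_val) + n_train,
                  test = seq((n_train + n_val + 1), n))
    if (n_train + n_val >= n) split$test <- integer(0)
    structure(
      list(instances = instances, template = template, basis = basis,
           split = split, seed = seed, offset_scale = offset_scale),
      class = "shape_population"
    )
  })
}

# landmark-only instance (no rasterization), used for large PCA populations
light_instance <- function(template, basis, coefficients) {
  gs <- template$grid_shape
  d <- length(gs)
  phi <- compose_field(basis, coefficients)
  pts <- as.matrix(template$landmarks[, coord_cols(d)])
  new_pts <- pts + interp_field(phi, pts)
  if (any(new_pts < 0) || any(sweep(new_pts, 2, gs - 1) > 0)) {
    stop(structure(
      class = c("shapearena_instance_rejected", "error", "condition"),
      list(message = "displaced landmark outside grid; reduce amplitudes", call = NULL)
    ))
  }
  lm <- template$landmarks
  lm[, coord_cols(d)] <- tibble::as_tibble(as.data.frame(new_pts))
  structure(
    list(landmarks = lm, label = NULL, appearance = NULL,
         true_coefficients = coefficients, true_intensity_offset = NULL),
    class = "shape_instance"
  )
}

#' @export
print.shape_population <- function(x, ...) {
  cat("<shape_population> n =", length(x$instances),
      "| splits:", paste(names(x$split), lengths(x$split), sep = "=", collapse = " "),
      "| k =", x$basis$k, "\n")
  invisible(x)
}

#' Flattened landmark shape matrix of (a subset of) a population
#'
#' @param population a [sample_population()] result.
#' @param which split name (`"train"`, `"validation"`, `"test"`) or integer
#'   indices; default all instances.
#' @return N x (d*m) matrix, one flattened shape per row; the landmark
#'   layout is attached as attribute `layout`.
#' @export
population_shapes <- function(population, which = NULL) {
  idx <- resolve_indices(population, which)
  shapes <- t(vapply(population$instances[idx],
                     function(inst) as.numeric(landmarks_flatten(inst$landmarks)),
                     numeric(nrow(population$template$landmarks) *
                               length(population$template$grid_shape))))
  attr(shapes, "layout") <- population$template$landmarks[, c("structure", "point_index")]
  attr(shapes, "d") <- length(population$template$grid_shape)
  shapes
}

#' Label images of (a subset of) a population
#' @inheritParams population_shapes
#' @return list of integer label arrays.
#' @export
population_labels <- function(population, which = NULL) {
  idx <- resolve_indices(population, which)
  lapply(population$instances[idx], function(inst) {
    if (is.null(inst$label)) {
      landmarks_to_label(inst$landmarks, population$template$grid_shape,
                         population$template$structure_order)
    } else inst$label
  })
}

#' Appearance images of (a subset of) a population
#' @inheritParams population_shapes
#' @return list of intensity arrays.
#' @export
population_appearances <- function(population, which = NULL) {
  idx <- resolve_indices(population, which)
  lapply(population$instances[idx], `[[`, "appearance")
}

resolve_indices <- function(population, which) {
  if (is.null(which)) return(seq_along(population$instances))
  if (is.character(which)) return(population$split[[which]])
  which
}
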