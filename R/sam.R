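# Statistical appearance models: shape PCA plus PCA of the intensities of
# images warped into the mean-shape frame ("shape-normalized"). Warps are
# thin-plate-spline scattered interpolations of the landmark displacements;
# warping back to the instance frame uses the spline fitted in the opposite
# direction, so no numerical field inversion is required.

tps_kernel <- function(r, d) {
  if (d == 2) {
    out <- r^2 * log(r)
    out[r < 1e-12] <- 0
    out
  } else {
    r
  }
}

tps_fit <- function(src, dst, ridge = 1e-8) {
  m <- nrow(src)
  d <- ncol(src)
  K <- tps_kernel(as.matrix(stats::dist(src)), d)
  P <- cbind(1, src)
  L <- rbind(cbind(K + ridge * diag(m), P),
             cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- rbind(dst, matrix(0, d + 1, d))
  sol <- solve(L, rhs)
  list(src = src, W = sol[seq_len(m), , drop = FALSE],
       A = sol[m + seq_len(d + 1), , drop = FALSE], d = d)
}

tps_eval <- function(fit, pts) {
  r <- sqrt(pmax(outer(rowSums(pts^2), rowSums(fit$src^2), `+`) -
                   2 * pts %*% t(fit$src), 0))
  tps_kernel(r, fit$d) %*% fit$W + cbind(1, pts) %*% fit$A
}

#' Fit a statistical appearance model (shape + shape-normalized intensity PCA)
#'
#' Each training appearance is resampled into the mean-shape frame by a
#' thin-plate spline interpolating the landmark displacements (mean shape
#' to instance shape), and PCA is run on the resulting shape-normalized
#' intensities; the shape itself is modelled by [fit_ssm()]. Generation
#' draws shape and appearance latents independently and warps the decoded
#' normalized image back to the decoded shape. Instances whose spline
#' system cannot be solved are skipped with a warning.
#'
#' @param shapes N x (d*m) shape matrix with landmark layout (e.g.
#'   [population_shapes()]).
#' @param appearances list of N intensity arrays on a common grid.
#' @param variability_threshold cumulative variance fraction for both PCAs.
#' @return object of class `appearance_model` with `shape_model`,
#'   `intensity_model`, `grid_shape`, `mean_points`.
#' @export
fit_sam <- function(shapes, appearances, variability_threshold = 0.95) {
  X <- as_shape_matrix(shapes)
  stopifnot(nrow(X) == length(appearances))
  grid_shape <- dim(appearances[[1]])
  d <- attr(X, "d")
  shape_model <- fit_ssm(X, variability_threshold)
  mean_pts <- matrix(shape_model$mean, ncol = d, byrow = TRUE)
  gc_pts <- grid_coords(grid_shape)
  norm_list <- list()
  used <- integer(0)
  for (i in seq_len(nrow(X))) {
    pts_i <- matrix(X[i, ], ncol = d, byrow = TRUE)
    norm_i <- tryCatch({
      Ti <- tps_fit(mean_pts, pts_i)
      interp_image(appearances[[i]], tps_eval(Ti, gc_pts))
    }, error = function(e) {
      warning("skipping instance ", i, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(norm_i)) {
      norm_list[[length(norm_list) + 1]] <- norm_i
      used <- c(used, i)
    }
  }
  intensity_model <- fit_ssm(do.call(rbind, norm_list), variability_threshold)
  structure(
    list(shape_model = shape_model, intensity_model = intensity_model,
         grid_shape = as.integer(grid_shape), mean_points = mean_pts,
         used_instances = used, d = d),
    class = "appearance_model"
  )
}

# resample an appearance into the mean-shape frame of a fitted SAM
sam_normalize <- function(model, shape, appearance) {
  pts <- matrix(as.numeric(shape), ncol = model$d, byrow = TRUE)
  Ti <- tps_fit(model$mean_points, pts)
  interp_image(appearance, tps_eval(Ti, grid_coords(model$grid_shape)))
}

# place a normalized (mean-frame) intensity vector onto a target shape
sam_denormalize <- function(model, normalized, target_shape) {
  pts <- matrix(as.numeric(target_shape), ncol = model$d, byrow = TRUE)
  S <- tps_fit(pts, model$mean_points)
  img <- array(normalized, dim = model$grid_shape)
  array(interp_image(img, tps_eval(S, grid_coords(model$grid_shape))),
        dim = model$grid_shape)
}

#' Reconstruct a (shape, appearance) pair with a fitted SAM
#'
#' @param model an [fit_sam()] result.
#' @param shape flattened landmark shape of the instance.
#' @param appearance the instance's intensity array.
#' @return list with `shape` (reconstructed landmark vector) and
#'   `appearance` (reconstructed intensity array on the same grid).
#' @export
reconstruct_sam <- function(model, shape, appearance) {
  recon_shape <- reconstruct(model$shape_model, project(model$shape_model, as.numeric(shape)))
  normalized <- sam_normalize(model, shape, appearance)
  recon_norm <- reconstruct(model$intensity_model,
                            project(model$intensity_model, normalized))
  list(shape = recon_shape,
       appearance = sam_denormalize(model, recon_norm, recon_shape))
}

#' Sample new appearances (with shapes) from a fitted SAM
#'
#' Shape and appearance latents are drawn independently from the
#' per-dimension Normal described by the training latents, decoded, and the
#' decoded normalized intensities are warped onto the decoded shape.
#'
#' @param model an [fit_sam()] result.
#' @param n number of samples.
#' @param seed integer seed.
#' @return list of `n` lists with `shape` and `appearance`.
#' @export
sample_sam <- function(model, n, seed = 1) {
  shapes <- sample_ssm(model$shape_model, n, seed = child_seed(seed, 1))
  norms <- sample_ssm(model$intensity_model, n, seed = child_seed(seed, 2))
  lapply(seq_len(n), function(i) {
    list(shape = shapes[i, ],
         appearance = sam_denormalize(model, norms[i, ], shapes[i, ]))
  })
}

#' @export
print.appearance_model <- function(x, ...) {
  cat("<appearance_model> shape p =", x$shape_model$p,
      "| intensity p =", x$intensity_model$p,
      "| grid", paste(x$grid_shape, collapse = "x"), "\n")
  invisible(x)
}
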