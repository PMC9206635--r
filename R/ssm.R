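# PCA-based statistical shape models on corresponded landmark vectors:
# x_new = x_mu + U z, with U from the eigen-decomposition of the training
# covariance (N x N Gram trick when d*m > N).

as_shape_matrix <- function(shapes) {
  if (is.matrix(shapes)) return(shapes)
  if (is.list(shapes)) {
    lens <- lengths(shapes)
    if (length(unique(lens)) != 1) stop("shapes have inconsistent lengths", call. = FALSE)
    m <- do.call(rbind, lapply(shapes, as.numeric))
    attr(m, "layout") <- attr(shapes[[1]], "layout")
    attr(m, "d") <- attr(shapes[[1]], "d")
    return(m)
  }
  stop("shapes must be a matrix or list of shape vectors", call. = FALSE)
}

EIGEN_FLOOR <- 1e-12

#' Fit a statistical shape model by PCA
#'
#' Centers the training shapes and eigen-decomposes their sample
#' covariance; when `d*m > N` the N x N Gram matrix is decomposed instead
#' and the modes recovered from it. The latent dimension `p` is the
#' smallest number of leading modes whose cumulative variance reaches
#' `variability_threshold` (eigenvalues below 1e-12 never count as rank).
#' Per-dimension mean/sd of the training latents are stored for the
#' fairness sampling protocol.
#'
#' @param shapes N x (d*m) matrix (rows = flattened landmark shapes, e.g.
#'   from [population_shapes()]) or list of shape vectors.
#' @param variability_threshold cumulative variance fraction (default 0.95).
#' @return object of class `pca_shape_model` with fields `mean`, `basis`
#'   (d*m x p, orthonormal), `mode_variances`, `p`, `latent_mean`,
#'   `latent_sd`, `total_variance`.
#' @export
fit_ssm <- function(shapes, variability_threshold = 0.95) {
  X <- as_shape_matrix(shapes)
  N <- nrow(X)
  if (N < 2) stop("need at least 2 shapes", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  dm <- ncol(X)
  if (dm > N) {
    G <- Xc %*% t(Xc) / (N - 1)
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > EIGEN_FLOOR
    lambda <- eg$values[keep]
    U <- t(Xc) %*% eg$vectors[, keep, drop = FALSE]
    U <- sweep(U, 2, sqrt((N - 1) * lambda), `/`)
  } else {
    C <- crossprod(Xc) / (N - 1)
    eg <- eigen(C, symmetric = TRUE)
    keep <- eg$values > EIGEN_FLOOR
    lambda <- eg$values[keep]
    U <- eg$vectors[, keep, drop = FALSE]
  }
  rank <- length(lambda)
  if (rank == 0) {
    warning("all training shapes are identical; model has p = 0")
    p <- 0L
    U <- matrix(0, dm, 0)
    lambda <- numeric(0)
  } else {
    cums <- cumsum(lambda) / sum(lambda)
    p <- as.integer(which(cums >= variability_threshold - 1e-12)[1])
    U <- U[, seq_len(p), drop = FALSE]
    lambda <- lambda[seq_len(p)]
  }
  model <- structure(
    list(mean = as.numeric(mu), basis = U, mode_variances = lambda, p = p,
         variability_threshold = variability_threshold,
         total_variance = if (rank == 0) 0 else sum(eg$values[eg$values > EIGEN_FLOOR]),
         n_train = N,
         layout = attr(X, "layout"), d = attr(X, "d")),
    class = "pca_shape_model"
  )
  Z <- project(model, X)
  model$latent_mean <- if (p > 0) colMeans(Z) else numeric(0)
  model$latent_sd <- if (p > 0) apply(Z, 2, stats::sd) else numeric(0)
  model
}

#' Project shapes into a PCA shape model's latent space
#'
#' `z = U' (x - x_mu)`.
#'
#' @param model a `pca_shape_model`.
#' @param shape one shape vector of length `d*m`, or an N x (d*m) matrix.
#' @return latent vector of length `p` (or N x p matrix).
#' @export
project <- function(model, shape) {
  UseMethod("project")
}

#' @export
project.pca_shape_model <- function(model, shape) {
  if (is.matrix(shape)) {
    if (ncol(shape) != length(model$mean)) stop("shape dimension mismatch", call. = FALSE)
    return(sweep(shape, 2, model$mean) %*% model$basis)
  }
  if (length(shape) != length(model$mean)) stop("shape dimension mismatch", call. = FALSE)
  as.numeric(crossprod(model$basis, as.numeric(shape) - model$mean))
}

#' Decode latent vectors of a PCA shape model into landmark shapes
#'
#' `x = x_mu + U z`; exact affine inverse of [project()] on the model
#' subspace.
#'
#' @param model a `pca_shape_model`.
#' @param z latent vector of length `p`, or an N x p matrix.
#' @return shape vector (or N x (d*m) matrix) carrying the model's landmark
#'   layout.
#' @export
reconstruct <- function(model, z) {
  UseMethod("reconstruct")
}

#' @export
reconstruct.pca_shape_model <- function(model, z) {
  if (is.matrix(z)) {
    if (ncol(z) != model$p) stop("latent dimension mismatch", call. = FALSE)
    out <- sweep(z %*% t(model$basis), 2, model$mean, `+`)
  } else {
    if (length(z) != model$p) stop("latent dimension mismatch", call. = FALSE)
    out <- as.numeric(model$mean + model$basis %*% as.numeric(z))
  }
  attr(out, "layout") <- model$layout
  attr(out, "d") <- model$d
  out
}

#' Sample new shapes from a PCA shape model
#'
#' Latents are drawn per dimension from `Normal(latent mean, latent sd)` of
#' the training latents (the fairness protocol shared by all model
#' families) and decoded with [reconstruct()].
#'
#' @param model a `pca_shape_model`.
#' @param n number of samples (>= 1).
#' @param latent_stats list with `mean` and `sd` vectors; defaults to the
#'   model's stored training-latent statistics.
#' @param seed integer seed.
#' @return n x (d*m) matrix of sampled shapes.
#' @export
sample_ssm <- function(model, n, latent_stats = NULL, seed = 1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (is.null(latent_stats)) {
    latent_stats <- list(mean = model$latent_mean, sd = model$latent_sd)
  }
  with_seed(seed, {
    Z <- matrix(rnorm(n * model$p, mean = rep(latent_stats$mean, each = n),
                      sd = rep(latent_stats$sd, each = n)), nrow = n)
    reconstruct(model, Z)
  })
}

#' @export
print.pca_shape_model <- function(x, ...) {
  cat("<", class(x)[1], "> p = ", x$p, " modes (threshold ",
      x$variability_threshold, "), ", length(x$mean), " shape dims, N = ",
      x$n_train, "\n", sep = "")
  invisible(x)
}

#' Tidy the mode spectrum of a PCA shape model
#'
#' @param x a `pca_shape_model`.
#' @param ... unused.
#' @return tibble with `mode`, `variance`, `proportion`, `cumulative`.
#' @export
tidy.pca_shape_model <- function(x, ...) {
  tv <- max(x$total_variance, .Machine$double.eps)
  tibble::tibble(
    mode = seq_len(x$p),
    variance = x$mode_variances,
    proportion = x$mode_variances / tv,
    cumulative = cumsum(x$mode_variances) / tv
  )
}

#' One-row summary of a PCA shape model
#'
#' @param x a `pca_shape_model`.
#' @param ... unused.
#' @return tibble with `p`, `n_train`, `shape_dims`, `total_variance`,
#'   `variability_threshold`.
#' @export
glance.pca_shape_model <- function(x, ...) {
  tibble::tibble(
    p = x$p, n_train = x$n_train, shape_dims = length(x$mean),
    total_variance = x$total_variance,
    variability_threshold = x$variability_threshold
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
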