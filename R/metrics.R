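# The evaluation suite: generalization ability, specificity, likeness
# (distance-based separability index), latent-space normality, compactness
# and the latent ambiguity score. All metrics are model-agnostic over the
# generative contract; the caller supplies the image-wise distance (ASSD
# for label outputs, L1 for intensities).

#' Generalization ability: mean reconstruction distance on held-out items
#'
#' `GA = (1/N_R) * sum_i dist(r_i, r_hat_i)` with `r_hat_i` the model's
#' reconstruction of held-out item `r_i`.
#'
#' @param model a fitted generative model (see [reconstruct_item()]).
#' @param held_out non-empty list of items disjoint from training.
#' @param dist distance function `dist(a, b) -> scalar >= 0`.
#' @return non-negative scalar (smaller is better).
#' @export
generalization_ability <- function(model, held_out, dist) {
  if (length(held_out) == 0) stop("held_out set is empty", call. = FALSE)
  mean(vapply(held_out, function(r) dist(r, reconstruct_item(model, r)), numeric(1)))
}

#' Specificity: mean distance of generated samples to their closest real item
#'
#' `(1/N_S) * sum_j min_i dist(r_i, s_j)` over `n_samples` generated items.
#' Zero iff every generated sample replays a real item exactly.
#'
#' @param model a fitted generative model (see [sample_items()]).
#' @param real non-empty list of real reference items.
#' @param n_samples number of generated samples (default `length(real)`,
#'   balancing the two classes).
#' @param dist distance function.
#' @param seed integer seed for the sampling.
#' @return non-negative scalar (smaller is better).
#' @export
specificity <- function(model, real, n_samples = length(real), dist, seed = 1) {
  if (length(real) == 0) stop("real set is empty", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  samples <- sample_items(model, n_samples, seed = seed)
  mean(vapply(samples, function(s) {
    min(vapply(real, function(r) dist(r, s), numeric(1)))
  }, numeric(1)))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum of the absolute difference of the two empirical CDFs,
#' evaluated over all breakpoints.
#'
#' @param a,b non-empty numeric samples.
#' @return statistic in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  x <- sort(unique(c(a, b)))
  Fa <- ecdf(a)(x)
  Fb <- ecdf(b)(x)
  max(abs(Fa - Fb))
}

# unordered distinct pair distances within a set; above `max_pairs` pairs a
# fixed-seed subsample bounds the quadratic cost
intra_class_distances <- function(items, dist, max_pairs = 19900, seed = 42) {
  n <- length(items)
  stopifnot(n >= 2)
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs) {
    pairs <- pairs[, with_seed(seed, sample.int(ncol(pairs), max_pairs)), drop = FALSE]
  }
  vapply(seq_len(ncol(pairs)), function(k) {
    dist(items[[pairs[1, k]]], items[[pairs[2, k]]])
  }, numeric(1))
}

between_class_distances <- function(real, synth, dist, max_pairs = 40000, seed = 43) {
  pairs <- as.matrix(expand.grid(seq_along(real), seq_along(synth)))
  if (nrow(pairs) > max_pairs) {
    pairs <- pairs[with_seed(seed, sample.int(nrow(pairs), max_pairs)), , drop = FALSE]
  }
  vapply(seq_len(nrow(pairs)), function(k) {
    dist(real[[pairs[k, 1]]], synth[[pairs[k, 2]]])
  }, numeric(1))
}

#' Likeness: distance-based separability index (DSI) of real vs synthetic
#'
#' Intra-class distance sets `{d_R}` and `{d_S}` (unordered distinct pairs
#' within each set) are compared with the between-class distance set
#' `{d_RS}` via two Kolmogorov-Smirnov statistics, whose average is the
#' DSI: `(KS({d_R}, {d_RS}) + KS({d_S}, {d_RS})) / 2`. Ranges over
#' \[0, 1\]; smaller values mean the synthetic set is harder to separate
#' from the real set (better).
#'
#' @param real,synth lists with at least 2 items each.
#' @param dist distance function.
#' @return DSI in \[0, 1\].
#' @export
likeness_dsi <- function(real, synth, dist) {
  stopifnot(length(real) >= 2, length(synth) >= 2)
  d_r <- intra_class_distances(real, dist)
  d_s <- intra_class_distances(synth, dist)
  d_rs <- between_class_distances(real, synth, dist)
  (ks_statistic(d_r, d_rs) + ks_statistic(d_s, d_rs)) / 2
}

#' Percentage of non-normally distributed latent dimensions
#'
#' Each latent dimension is tested with a Shapiro-Wilk test; the fraction
#' of dimensions with `p < alpha` (rejected normality) is reported as a
#' percentage. Constant dimensions are counted as non-normal with a
#' warning.
#'
#' @param latents N x p matrix of encoded samples (N >= 8 for test
#'   validity).
#' @param alpha significance level (default 0.05, reported alongside).
#' @return percentage in \[0, 100\] with attribute `alpha`.
#' @export
normality_fraction <- function(latents, alpha = 0.05) {
  latents <- as.matrix(latents)
  if (nrow(latents) < 8) stop("need at least 8 samples per dimension", call. = FALSE)
  if (ncol(latents) < 1) stop("need at least one latent dimension", call. = FALSE)
  rejected <- vapply(seq_len(ncol(latents)), function(j) {
    v <- latents[, j]
    if (stats::sd(v) < 1e-12) {
      warning("latent dimension ", j, " is constant; counted as non-normal")
      return(TRUE)
    }
    shapiro.test(v)$p.value < alpha
  }, logical(1))
  out <- 100 * mean(rejected)
  attr(out, "alpha") <- alpha
  out
}

#' Latent ambiguity score (LAS)
#'
#' `LAS = D / D_base` with `D` the mean latent distance between an item's
#' encoding and the encoding of its own reconstruction,
#' `mean ||f(r) - f(g(f(r)))||_2`, and `D_base` the mean pairwise encoded
#' distance `mean_{i != j} ||f(r_i) - f(r_j)||_2`. A score near 0 means
#' reconstructions map back to their own latent codes; linear PCA models
#' attain exactly 0 because projection after reconstruction is the
#' identity on the model subspace.
#'
#' @param model a fitted generative model exposing [encode()] and
#'   [reconstruct_item()].
#' @param real list of at least 2 items.
#' @return non-negative scalar.
#' @export
latent_ambiguity_score <- function(model, real) {
  stopifnot(length(real) >= 2)
  enc <- lapply(real, function(r) as.numeric(encode(model, r)))
  enc2 <- lapply(real, function(r) {
    as.numeric(encode(model, reconstruct_item(model, r)))
  })
  D <- mean(mapply(function(a, b) sqrt(sum((a - b)^2)), enc, enc2))
  E <- do.call(rbind, enc)
  pd <- as.matrix(stats::dist(E))
  n <- nrow(E)
  D_base <- sum(pd) / (n * (n - 1))
  if (D_base < 1e-12) stop("all encodings identical; LAS undefined", call. = FALSE)
  D / D_base
}

#' Compactness: latent dimensionality of a fitted model
#'
#' PCA models report the number of modes reaching the variability
#' threshold; network models report their configured latent size (the
#' split-latent ADAE reports the shape and appearance dimensions as a pair,
#' conventionally printed `dim_s+dim_a`, see [format_compactness()]).
#'
#' @param model a fitted generative model.
#' @return integer (or integer pair for split latents).
#' @export
compactness <- function(model) UseMethod("compactness")

#' @export
compactness.pca_shape_model <- function(model) model$p

#' @export
compactness.appearance_model <- function(model) {
  c(model$shape_model$p, model$intensity_model$p)
}

#' @export
compactness.default <- function(model) latent_dim(model)

#' Conventional display of a (possibly split) compactness value
#'
#' @param x result of [compactness()].
#' @return string such as `"512"` or `"1024+64"`.
#' @export
format_compactness <- function(x) paste(x, collapse = "+")
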