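# Training losses: weighted generalized Dice (label outputs), SSIM
# (intensity outputs), the closed-form KL divergence against Normal(0, 1),
# binary cross-entropy adversarial terms, and the diffusion + L1
# displacement regularizer (both terms weighted by 10). Each loss has a
# matching internal gradient used by the training loop (internally images
# are channels-first C x voxels matrices); the exported functions operate
# on plain channels-last arrays.

as_channels_first <- function(x) {
  d <- dim(x)
  t(matrix(x, ncol = d[length(d)]))
}

#' Weighted generalized Dice loss
#'
#' `1 - 2 * sum_l w_l sum_v p t / sum_l w_l sum_v (p + t)` with per-class
#' weights defaulting to the inverse squared class volume of the target
#' (volumes floored at one voxel so absent classes stay finite). 0 for
#' identical one-hots, 1 for disjoint single-class masks; always in
#' \[0, 1\].
#'
#' @param pred,target one-hot arrays (channels last) of the same shape;
#'   `pred` may be soft.
#' @param weights optional per-class weights (all zero is an error).
#' @return scalar in \[0, 1\].
#' @export
generalized_dice_loss <- function(pred, target, weights = NULL) {
  stopifnot_grid_match(pred, target)
  gdl_core(as_channels_first(pred), as_channels_first(target), weights)$loss
}

# P, T_: C x V channels-first
gdl_core <- function(P, T_, weights = NULL) {
  if (is.null(weights)) {
    vol <- rowSums(T_)
    weights <- 1 / pmax(vol, 1)^2
  }
  if (all(weights == 0)) stop("all-zero Dice class weights", call. = FALSE)
  inter <- rowSums(P * T_)
  tot <- rowSums(P) + rowSums(T_)
  A <- sum(weights * inter)
  Bd <- sum(weights * tot)
  loss <- 1 - 2 * A / Bd
  grad <- function() {
    # d loss / d P[l, v] = (-2 w_l t Bd + 2 A w_l) / Bd^2
    (-2 * (T_ * (weights * Bd)) + 2 * A * weights) / Bd^2
  }
  list(loss = loss, grad = grad)
}

# softmax + generalized Dice with gradient w.r.t. logits, per batch item
gdl_softmax_batch <- function(logits, target_mat, nvox, B) {
  total <- 0
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  for (b in seq_len(B)) {
    cols <- seq_len(nvox) + (b - 1) * nvox
    P <- softmax_cols(logits[, cols, drop = FALSE])
    r <- gdl_core(P, target_mat[, cols, drop = FALSE])
    total <- total + r$loss
    dP <- r$grad()
    dlogits[, cols] <- P * (dP - rep(colSums(dP * P), each = nrow(P)))
  }
  list(loss = total / B, dlogits = dlogits / B)
}

# plain (already-probability) channels + generalized Dice, per batch item
gdl_probs_batch <- function(probs, target_mat, nvox, B) {
  total <- 0
  dP_all <- matrix(0, nrow(probs), ncol(probs))
  for (b in seq_len(B)) {
    cols <- seq_len(nvox) + (b - 1) * nvox
    r <- gdl_core(probs[, cols, drop = FALSE], target_mat[, cols, drop = FALSE])
    total <- total + r$loss
    dP_all[, cols] <- r$grad()
  }
  list(loss = total / B, dP = dP_all / B)
}

# ---- SSIM ------------------------------------------------------------------

box_filter_matrix <- function(n, half = 3) {
  idx <- seq_len(n)
  K <- (abs(outer(idx, idx, "-")) <= half) * 1
  K / rowSums(K)
}

ssim_maps <- function(x, y, C1 = 0.01^2, C2 = 0.03^2) {
  gs <- dim(x)
  filt <- function(a) {
    for (ax in seq_along(gs)) a <- ttm(a, box_filter_matrix(gs[ax]), ax)
    a
  }
  mu_x <- filt(x); mu_y <- filt(y)
  sxx <- filt(x * x) - mu_x^2
  syy <- filt(y * y) - mu_y^2
  sxy <- filt(x * y) - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + C1
  A2 <- 2 * sxy + C2
  B1 <- mu_x^2 + mu_y^2 + C1
  B2 <- sxx + syy + C2
  list(S = (A1 * A2) / (B1 * B2), mu_x = mu_x, mu_y = mu_y,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, gs = gs)
}

ssim_filter_adjoint <- function(a, gs) {
  for (ax in seq_along(gs)) a <- ttm(a, t(box_filter_matrix(gs[ax])), ax)
  a
}

#' Structural-similarity loss `1 - mean(SSIM)`
#'
#' Local statistics over a 7-wide uniform window per axis (renormalized at
#' the borders), standard constants `C1 = 0.01^2`, `C2 = 0.03^2` for
#' intensities in \[0, 1\]. 0 for identical images.
#'
#' @param pred,target numeric arrays on the same grid.
#' @return scalar loss.
#' @export
ssim_loss <- function(pred, target) {
  stopifnot_grid_match(pred, target)
  if (any(!is.finite(pred)) || any(!is.finite(target))) {
    stop("non-finite SSIM inputs", call. = FALSE)
  }
  1 - mean(ssim_maps(pred, target)$S)
}

# gradient of 1 - mean(SSIM(x, y)) w.r.t. x (one item)
ssim_loss_grad <- function(x, y) {
  m <- ssim_maps(x, y)
  gs <- m$gs
  P <- prod(gs)
  S <- m$S
  dS_dmu <- 2 * m$mu_y * m$A2 / (m$B1 * m$B2) - 2 * m$mu_x * S / m$B1
  dS_dsxx <- -S / m$B2
  dS_dsxy <- 2 * m$A1 / (m$B1 * m$B2)
  adj <- function(a) ssim_filter_adjoint(a, gs)
  dx <- adj(dS_dmu) +
    2 * x * adj(dS_dsxx) - 2 * adj(m$mu_x * dS_dsxx) +
    y * adj(dS_dsxy) - adj(m$mu_y * dS_dsxy)
  list(loss = 1 - mean(S), grad = -dx / P)
}

# pred_mat, target_mat: 1 x (nvox*B) channels-first intensity activations
ssim_batch <- function(pred_mat, target_mat, gs, B) {
  nvox <- prod(gs)
  total <- 0
  dP <- matrix(0, 1, ncol(pred_mat))
  for (b in seq_len(B)) {
    cols <- seq_len(nvox) + (b - 1) * nvox
    r <- ssim_loss_grad(array(pred_mat[1, cols], gs), array(target_mat[1, cols], gs))
    total <- total + r$loss
    dP[1, cols] <- as.vector(r$grad)
  }
  list(loss = total / B, dP = dP / B)
}

# ---- KL --------------------------------------------------------------------

#' Kullback-Leibler divergence of diagonal Gaussians against Normal(0, 1)
#'
#' Closed form `0.5 * sum_j (mu^2 + exp(logvar) - 1 - logvar)`, averaged
#' over the batch (rows).
#'
#' @param mu,logvar B x p matrices (or vectors) of means and log-variances.
#' @return scalar loss.
#' @export
kl_loss <- function(mu, logvar) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("non-finite KL inputs", call. = FALSE)
  }
  mean(rowSums(0.5 * (mu^2 + exp(logvar) - 1 - logvar)))
}

kl_loss_grad <- function(mu, logvar) {
  B <- nrow(mu)
  list(loss = kl_loss(mu, logvar),
       dmu = mu / B,
       dlogvar = 0.5 * (exp(logvar) - 1) / B)
}

# ---- adversarial -----------------------------------------------------------

bce_logits <- function(logits, target) {
  # numerically stable binary cross-entropy with logits
  mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
}

bce_logits_grad <- function(logits, target) {
  (sigmoid(logits) - target) / length(logits)
}

#' Adversarial (GAN) loss terms in binary cross-entropy form
#'
#' The generator term scores the fake logits against the "real" label; the
#' discriminator term averages real-vs-1 and fake-vs-0 cross-entropies.
#'
#' @param disc_out_real,disc_out_fake discriminator logits.
#' @return list with `gen_term` and `disc_term`.
#' @export
adversarial_losses <- function(disc_out_real, disc_out_fake) {
  if (any(!is.finite(disc_out_real)) || any(!is.finite(disc_out_fake))) {
    stop("non-finite discriminator outputs", call. = FALSE)
  }
  list(
    gen_term = bce_logits(disc_out_fake, 1),
    disc_term = (bce_logits(disc_out_real, 1) + bce_logits(disc_out_fake, 0)) / 2
  )
}

# ---- displacement regularizer ----------------------------------------------

#' Diffusion + L1 displacement-field regularizer
#'
#' `10 * mean(squared forward-difference gradients) +
#'  10 * mean_v sum_channels |u|`; both terms carry the fixed weight of 10.
#' The gradient mean is taken over all axes, channels and voxels (forward
#' differences, last slice per axis dropped), the L1 mean over voxels after
#' summing channels, so a constant field `c` in `d` channels scores
#' `10 * d * |c|`.
#'
#' @param field displacement array `c(grid_shape, d)`.
#' @return non-negative scalar.
#' @export
displacement_regularizer <- function(field) {
  fd <- dim(field)
  gs <- fd[-length(fd)]
  reg_core(t(matrix(field, ncol = fd[length(fd)])), gs, 1)$loss
}

# field_mat: d x (nvox*B) channels-first; returns loss averaged per item
reg_core <- function(field_mat, gs, B) {
  d <- nrow(field_mat)
  nvox <- prod(gs)
  ndiff <- 0
  sq_sum <- 0
  dF <- matrix(0, d, ncol(field_mat))
  for (ax in seq_along(gs)) {
    n <- gs[ax]
    D <- diag(n)[-1, , drop = FALSE] - diag(n)[-n, , drop = FALSE] # forward diff
    for (ch in seq_len(d)) {
      a <- array(field_mat[ch, ], c(gs, B))
      g <- ttm(a, D, ax)
      sq_sum <- sq_sum + sum(g^2)
      ndiff <- ndiff + length(g) / B
      back <- ttm(g, t(D), ax)
      dF[ch, ] <- dF[ch, ] + 2 * as.vector(back)
    }
  }
  diffusion <- sq_sum / (ndiff * B)
  l1 <- sum(abs(field_mat)) / (nvox * B)
  loss <- 10 * diffusion + 10 * l1
  grad <- 10 * dF / (ndiff * B) + 10 * sign(field_mat) / (nvox * B)
  list(loss = loss, grad = grad)
}
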