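# The four autoencoder families (AE, VAE, AE-GAN, DAE/ADAE) behind the same
# generative contract as the statistical models. All kinds share one fixed
# architecture: encoder (and discriminator) = three stride-2 convolutions
# with channels [in, 20, 40, 80] plus a fully connected layer to the
# latent; decoder = fully connected + three {linear upsampling, conv}
# stages with channels [80, 40, 20, out]. Model-specific parts: the VAE's
# second latent head (mean + log-variance), the AE-GAN's discriminator, and
# the DAE/ADAE decoders that emit a displacement field (plus intensity
# offset) applied to a fixed template.

NETWORK_KINDS <- c("ae", "vae", "aegan", "dae", "adae")

#' Specify a network generative model
#'
#' @param kind one of `"ae"`, `"vae"`, `"aegan"`, `"dae"`, `"adae"`.
#' @param grid_shape spatial extent per axis (2D or 3D); each axis must be
#'   divisible by 8 (three stride-2 stages).
#' @param in_channels input channels: `L + 1` for one-hot label images, 1
#'   for intensity images.
#' @param out_channels output channels; defaults to `in_channels`
#'   (DAE/ADAE decoders emit `length(grid_shape)` displacement channels
#'   regardless).
#' @param latent_dim latent size (desk default 32; paper-scale runs use 512
#'   for 2D and 1024 for 3D via this argument).
#' @param appearance_latent_dim ADAE only: appearance part of the split
#'   latent `[z_s, z_a]` (default 64 at paper scale, 8 at desk scale).
#' @param data_mode `"label"` (generalized Dice reconstruction loss) or
#'   `"intensity"` (SSIM loss).
#' @param loss_weights named weights: `reconstruction`, `kl`,
#'   `adversarial` (all default 1; the displacement regularizer carries its
#'   fixed internal weight of 10).
#' @param seed seed for weight initialization.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(kind, grid_shape, in_channels,
                         out_channels = in_channels,
                         latent_dim = 32, appearance_latent_dim = 8,
                         data_mode = c("label", "intensity"),
                         loss_weights = c(reconstruction = 1, kl = 1, adversarial = 1),
                         seed = 1) {
  kind <- match.arg(kind, NETWORK_KINDS)
  data_mode <- match.arg(data_mode)
  stopifnot(latent_dim >= 1, in_channels >= 1)
  if (kind == "adae" && data_mode != "intensity") {
    stop("adae models intensities (template + offset); use data_mode = 'intensity'",
         call. = FALSE)
  }
  structure(
    list(kind = kind, grid_shape = as.integer(grid_shape),
         spatial_dims = length(grid_shape),
         in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         latent_dim = as.integer(latent_dim),
         appearance_latent_dim = as.integer(appearance_latent_dim),
         data_mode = data_mode, loss_weights = loss_weights, seed = seed),
    class = "network_spec"
  )
}

is_stochastic_kind <- function(kind) kind %in% c("vae", "dae", "adae")

make_encoder <- function(gs, cin, out_dim) {
  list(
    new_conv(gs, cin, 20, stride = 2), new_relu(),
    new_conv(gs %/% 2, 20, 40, stride = 2), new_relu(),
    new_conv(gs %/% 4, 40, 80, stride = 2), new_relu(),
    new_flatten(gs %/% 8, 80),
    new_dense(prod(gs %/% 8) * 80, out_dim, init_sd = 0.01)
  )
}

make_decoder <- function(gs, p, cout) {
  list(
    new_dense(p, prod(gs %/% 8) * 80),
    new_unflatten(gs %/% 8, 80), new_relu(),
    new_upsample(gs %/% 8), new_conv(gs %/% 4, 80, 40), new_relu(),
    new_upsample(gs %/% 4), new_conv(gs %/% 2, 40, 20), new_relu(),
    new_upsample(gs %/% 2), new_conv(gs, 20, cout, init_sd = 0.01)
  )
}

#' Build a network generative model from its specification
#'
#' @param spec a [network_spec()].
#' @return untrained model of class `arena_network` (train with [train()];
#'   DAE/ADAE receive their fixed template from the training set unless set
#'   beforehand).
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  gs <- spec$grid_shape
  if (any(gs %% 8 != 0)) {
    stop("grid_shape must be divisible by 8 per spatial axis (three stride-2 stages)",
         call. = FALSE)
  }
  d <- spec$spatial_dims
  p <- spec$latent_dim
  pa <- spec$appearance_latent_dim
  with_seed(spec$seed, {
    stoch <- is_stochastic_kind(spec$kind)
    enc_out <- switch(spec$kind,
      adae = 2 * (p + pa),
      if (stoch) 2 * p else p
    )
    model <- list(
      spec = spec, kind = spec$kind, gs = gs, nvox = prod(gs),
      stochastic = stoch,
      enc = make_encoder(gs, spec$in_channels, enc_out),
      dec = switch(spec$kind,
        dae = make_decoder(gs, p, d),
        adae = make_decoder(gs, p, d),
        make_decoder(gs, p, spec$out_channels)
      ),
      dec_a = if (spec$kind == "adae") make_decoder(gs, pa, 1),
      disc = if (spec$kind == "aegan") make_encoder(gs, spec$in_channels, 1),
      template_mat = NULL, template_label = NULL,
      trained = FALSE, latent_stats = NULL, loss_history = numeric(0)
    )
    class(model) <- c(paste0("arena_", spec$kind), "arena_network")
    model
  })
}

#' Number of trainable parameters of a network model
#' @param model an `arena_network`.
#' @return integer count over encoder, decoder(s) and discriminator.
#' @export
n_parameters <- function(model) {
  n_layer_params(model$enc) + n_layer_params(model$dec) +
    (if (!is.null(model$dec_a)) n_layer_params(model$dec_a) else 0) +
    (if (!is.null(model$disc)) n_layer_params(model$disc) else 0)
}

#' @export
print.arena_network <- function(x, ...) {
  cat("<arena_network:", x$kind, "> grid",
      paste(x$gs, collapse = "x"), "| latent", x$spec$latent_dim,
      if (x$kind == "adae") paste0("+", x$spec$appearance_latent_dim),
      "|", n_parameters(x), "parameters |",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

# ---- data conversion -------------------------------------------------------

# channels-first C x voxels matrix from a native item
item_to_mat <- function(model, x) {
  if (is.matrix(x) && ncol(x) == model$nvox) return(x)
  if (model$spec$data_mode == "label") {
    C <- model$spec$in_channels
    m <- matrix(0, C, model$nvox)
    m[cbind(as.vector(x) + 1L, seq_len(model$nvox))] <- 1
    m
  } else {
    matrix(as.vector(x), nrow = 1)
  }
}

mat_to_item <- function(model, m) {
  gs <- model$gs
  if (model$spec$data_mode == "label") {
    onehot_to_label(array(t(m), c(gs, nrow(m))))
  } else {
    array(m[1, ], gs)
  }
}

# ---- forward / backward per kind ------------------------------------------

split_latent_head <- function(H, p) {
  list(mu = H[, seq_len(p), drop = FALSE],
       logvar = pmin(pmax(H[, p + seq_len(p), drop = FALSE], -10), 10))
}

# One loss + gradient evaluation on a batch (target = input X, NoB x C).
# Draws reparameterization noise from the current RNG state.
network_step <- function(model, X, B) {
  spec <- model$spec
  w <- spec$loss_weights
  nvox <- model$nvox
  ef <- seq_forward(model$enc, X, B)
  H <- ef$out
  grads <- list()
  loss_parts <- c()

  if (model$stochastic) {
    p_all <- ncol(H) / 2
    sl <- split_latent_head(H, p_all)
    eps <- matrix(rnorm(B * p_all), B, p_all)
    Z <- sl$mu + exp(sl$logvar / 2) * eps
    klg <- kl_loss_grad(sl$mu, sl$logvar)
    loss_parts["kl"] <- w[["kl"]] * klg$loss
  } else {
    Z <- H
  }

  if (spec$kind == "adae") {
    p <- spec$latent_dim
    Zs <- Z[, seq_len(p), drop = FALSE]
    Za <- Z[, p + seq_len(spec$appearance_latent_dim), drop = FALSE]
    df <- seq_forward(model$dec, Zs, B)
    da <- seq_forward(model$dec_a, Za, B)
    ws <- warp_sample(model$template_mat, model$gs, df$out, B, offset = da$out)
    rec <- ssim_batch(ws$out, X, model$gs, B)
    reg <- reg_core(df$out, model$gs, B)
    loss_parts["reconstruction"] <- w[["reconstruction"]] * rec$loss
    loss_parts["regularizer"] <- reg$loss
    wb <- warp_sample_backward(ws$cache, w[["reconstruction"]] * rec$dP)
    bdec <- seq_backward(model$dec, df$caches, wb$dField + reg$grad)
    bdeca <- seq_backward(model$dec_a, da$caches, wb$dOffset)
    grads$dec <- bdec$grads
    grads$dec_a <- bdeca$grads
    dZ <- cbind(bdec$dX, bdeca$dX)
  } else if (spec$kind == "dae") {
    df <- seq_forward(model$dec, Z, B)
    if (spec$data_mode == "label") {
      ws <- warp_sample(model$template_mat, model$gs, df$out, B)
      rec <- gdl_probs_batch(ws$out, X, nvox, B)
      dOut <- w[["reconstruction"]] * rec$dP
    } else {
      ws <- warp_sample(model$template_mat, model$gs, df$out, B)
      rec <- ssim_batch(ws$out, X, model$gs, B)
      dOut <- w[["reconstruction"]] * rec$dP
    }
    reg <- reg_core(df$out, model$gs, B)
    loss_parts["reconstruction"] <- w[["reconstruction"]] * rec$loss
    loss_parts["regularizer"] <- reg$loss
    wb <- warp_sample_backward(ws$cache, dOut)
    bdec <- seq_backward(model$dec, df$caches, wb$dField + reg$grad)
    grads$dec <- bdec$grads
    dZ <- bdec$dX
  } else {
    df <- seq_forward(model$dec, Z, B)
    if (spec$data_mode == "label") {
      rec <- gdl_softmax_batch(df$out, X, nvox, B)
      dlogits <- w[["reconstruction"]] * rec$dlogits
    } else {
      P <- sigmoid(df$out)
      rec <- ssim_batch(P, X, model$gs, B)
      dlogits <- w[["reconstruction"]] * rec$dP * P * (1 - P)
    }
    loss_parts["reconstruction"] <- w[["reconstruction"]] * rec$loss

    if (spec$kind == "aegan") {
      fake_in <- if (spec$data_mode == "label") softmax_cols(df$out) else sigmoid(df$out)
      dreal <- seq_forward(model$disc, X, B)
      dfake <- seq_forward(model$disc, fake_in, B)
      adv <- adversarial_losses(as.vector(dreal$out), as.vector(dfake$out))
      loss_parts["adversarial"] <- w[["adversarial"]] * adv$gen_term
      loss_parts["disc"] <- adv$disc_term
      # discriminator grads (not propagated into the generator)
      g_real <- seq_backward(model$disc, dreal$caches,
                             matrix(bce_logits_grad(as.vector(dreal$out), 1) / 2, ncol = 1))
      g_fake <- seq_backward(model$disc, dfake$caches,
                             matrix(bce_logits_grad(as.vector(dfake$out), 0) / 2, ncol = 1))
      grads$disc <- add_grad_lists(g_real$grads, g_fake$grads)
      # generator adversarial gradient, through the discriminator input
      g_gen <- seq_backward(model$disc, dfake$caches,
                            matrix(w[["adversarial"]] *
                                     bce_logits_grad(as.vector(dfake$out), 1), ncol = 1))
      dFake <- g_gen$dX
      if (spec$data_mode == "label") {
        dlogits <- dlogits + fake_in *
          (dFake - rep(colSums(dFake * fake_in), each = nrow(fake_in)))
      } else {
        dlogits <- dlogits + dFake * fake_in * (1 - fake_in)
      }
    }
    bdec <- seq_backward(model$dec, df$caches, dlogits)
    grads$dec <- bdec$grads
    dZ <- bdec$dX
  }

  if (model$stochastic) {
    dmu <- dZ + klg$dmu * w[["kl"]]
    dlv <- dZ * eps * 0.5 * exp(sl$logvar / 2) + klg$dlogvar * w[["kl"]]
    dH <- cbind(dmu, dlv)
  } else {
    dH <- dZ
  }
  benc <- seq_backward(model$enc, ef$caches, dH)
  grads$enc <- benc$grads
  gen_loss <- sum(loss_parts[setdiff(names(loss_parts), "disc")])
  list(loss = gen_loss, parts = loss_parts, grads = grads)
}

add_grad_lists <- function(a, b) {
  lapply(seq_along(a), function(i) {
    if (length(a[[i]]) == 0) return(a[[i]])
    out <- lapply(names(a[[i]]), function(nm) a[[i]][[nm]] + b[[i]][[nm]])
    names(out) <- names(a[[i]])
    out
  })
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(model) {
  st <- list(t = 0)
  for (part in c("enc", "dec", "dec_a", "disc")) {
    if (is.null(model[[part]])) next
    st[[part]] <- lapply(model[[part]], function(l) {
      lapply(l$params, function(p) list(m = p * 0, v = p * 0))
    })
  }
  st
}

adam_update <- function(model, opt, grads, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (part in names(grads)) {
    layers <- model[[part]]
    for (i in seq_along(layers)) {
      for (nm in names(layers[[i]]$params)) {
        g <- grads[[part]][[i]][[nm]]
        if (nm == "W") g <- g + wd * layers[[i]]$params[[nm]]
        s <- opt[[part]][[i]][[nm]]
        s$m <- beta1 * s$m + (1 - beta1) * g
        s$v <- beta2 * s$v + (1 - beta2) * g^2
        opt[[part]][[i]][[nm]] <- s
        layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
          lr * (s$m / corr1) / (sqrt(s$v / corr2) + eps)
      }
    }
    model[[part]] <- layers
  }
  list(model = model, opt = opt)
}

# ---- training --------------------------------------------------------------

#' Training configuration for network models
#'
#' Adam with the stated defaults; weight decay is kept small but non-zero
#' (its Gaussian prior on the weights also nudges latent distributions
#' toward normality).
#'
#' @param epochs training epochs (desk default 40).
#' @param batch_size minibatch size (default 8).
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay L2 penalty on conv/dense weights (default 1e-5).
#' @param seed seed controlling shuffling and reparameterization noise.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 40, batch_size = 8, learning_rate = 1e-3,
                         weight_decay = 1e-5, seed = 1) {
  stopifnot(epochs > 0, batch_size > 0, learning_rate > 0, weight_decay >= 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = seed),
            class = "train_config")
}

#' Train a network generative model
#'
#' Runs seeded minibatch Adam on the model's composite loss
#' (reconstruction, plus KL for VAE/DAE/ADAE, plus the adversarial terms
#' for AE-GAN, plus the displacement regularizer for DAE/ADAE). For
#' DAE/ADAE the fixed template (voxelwise majority label, or mean
#' intensity) is computed from the training set before the first step.
#' After training, the per-dimension mean/sd of the training latents are
#' stored for the fairness sampling protocol. Identical seeds give
#' identical training runs.
#'
#' @param model an untrained (or previously trained) `arena_network`.
#' @param data a [sample_population()] (its train split is used, labels or
#'   appearances per the spec's `data_mode`) or a list of image arrays.
#' @param config a [train_config()].
#' @return the trained model, with `loss_history` (one mean loss per epoch).
#' @export
train <- function(model, data, config = train_config()) {
  UseMethod("train")
}

#' @export
train.arena_network <- function(model, data, config = train_config()) {
  if (inherits(data, "shape_population")) {
    data <- if (model$spec$data_mode == "label") {
      population_labels(data, "train")
    } else {
      population_appearances(data, "train")
    }
  }
  if (length(data) == 0) stop("training set is empty", call. = FALSE)
  mats <- lapply(data, function(x) item_to_mat(model, x))

  if (model$kind %in% c("dae", "adae") && is.null(model$template_mat)) {
    if (model$spec$data_mode == "label") {
      # medoid training label (squared one-hot distance): a real instance,
      # so every structure present in the data is present in the template
      X <- vapply(mats, as.vector, numeric(length(mats[[1]])))
      G <- crossprod(X)
      d2 <- outer(diag(G), diag(G), `+`) - 2 * G
      model$template_mat <- mats[[which.min(rowSums(d2))]]
      model$template_label <- array(
        as.integer(max.col(t(model$template_mat), ties.method = "first") - 1L),
        model$gs)
    } else {
      model$template_mat <- Reduce(`+`, mats) / length(mats)
    }
  }

  opt <- adam_init(model)
  history <- numeric(config$epochs)
  with_seed(config$seed, {
    n <- length(mats)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        B <- length(idx)
        X <- do.call(cbind, mats[idx])
        st <- network_step(model, X, B)
        if (!is.finite(st$loss)) {
          stop("non-finite loss at epoch ", ep, "; lower the learning rate",
               call. = FALSE)
        }
        upd <- adam_update(model, opt, st$grads,
                           lr = config$learning_rate, wd = config$weight_decay)
        model <- upd$model
        opt <- upd$opt
        losses <- c(losses, st$loss)
      }
      history[ep] <- mean(losses)
    }
  })
  model$loss_history <- c(model$loss_history, history)
  model$trained <- TRUE
  Zs <- t(vapply(mats, function(m) encode_mat(model, m), numeric(total_latent_dim(model))))
  model$latent_stats <- list(mean = colMeans(Zs), sd = apply(Zs, 2, stats::sd))
  model
}

total_latent_dim <- function(model) {
  if (model$kind == "adae") model$spec$latent_dim + model$spec$appearance_latent_dim
  else model$spec$latent_dim
}

encode_mat <- function(model, m) {
  H <- seq_forward(model$enc, m, 1)$out
  if (model$stochastic) {
    as.numeric(split_latent_head(H, ncol(H) / 2)$mu)
  } else {
    as.numeric(H)
  }
}

decode_vec <- function(model, z) {
  spec <- model$spec
  if (model$kind == "adae") {
    p <- spec$latent_dim
    field <- seq_forward(model$dec, matrix(z[seq_len(p)], 1), 1)$out
    offs <- seq_forward(model$dec_a, matrix(z[p + seq_len(spec$appearance_latent_dim)], 1), 1)$out
    warp_sample(model$template_mat, model$gs, field, 1, offset = offs)$out
  } else if (model$kind == "dae") {
    field <- seq_forward(model$dec, matrix(z, 1), 1)$out
    warp_sample(model$template_mat, model$gs, field, 1)$out
  } else {
    out <- seq_forward(model$dec, matrix(z, 1), 1)$out
    if (spec$data_mode == "label") softmax_cols(out) else sigmoid(out)
  }
}

# ---- generative contract ---------------------------------------------------

#' @export
encode.arena_network <- function(model, x, ...) {
  if (!model$trained) stop("model is untrained", call. = FALSE)
  encode_mat(model, item_to_mat(model, x))
}

#' @export
decode.arena_network <- function(model, z, ...) {
  if (!model$trained) stop("model is untrained", call. = FALSE)
  mat_to_item(model, decode_vec(model, z))
}

#' @export
reconstruct_item.arena_network <- function(model, x, ...) {
  decode(model, encode(model, x))
}

#' @export
sample_items.arena_network <- function(model, n, latent_stats = NULL, seed = 1, ...) {
  if (!model$trained) stop("model is untrained", call. = FALSE)
  if (is.null(latent_stats)) latent_stats <- model$latent_stats
  p <- length(latent_stats$mean)
  with_seed(seed, {
    Z <- matrix(rnorm(n * p, mean = rep(latent_stats$mean, each = n),
                      sd = rep(latent_stats$sd, each = n)), n, p)
    lapply(seq_len(n), function(i) mat_to_item(model, decode_vec(model, Z[i, ])))
  })
}

#' @export
latent_dim.arena_network <- function(model) {
  if (model$kind == "adae") {
    c(model$spec$latent_dim, model$spec$appearance_latent_dim)
  } else {
    model$spec$latent_dim
  }
}
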