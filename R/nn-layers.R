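# Minimal neural-network primitives with hand-derived backpropagation.
#
# Spatial activations are stored channels-first as C x (voxels * batch)
# matrices with column index = voxel + (b - 1) * n_voxels (voxel fastest,
# column-major over the grid). Convolution gathers shifted columns
# (contiguous memcpy, compiled), multiplies with the kernel block via BLAS,
# and scatter-adds gradients on the way back. Latent-side activations
# (dense layers) are B x features matrices. All spatial primitives are
# dimension-generic (2D and 3D).

`%||%` <- function(a, b) if (is.null(a)) b else a

lin_index <- function(pos0, dims) {
  # 0-based positions (n x d) -> 1-based column-major linear index
  strides <- cumprod(c(1, dims[-length(dims)]))
  as.integer(1 + pos0 %*% strides)
}

batch_cols <- function(idx, nvox_in, B) {
  as.integer(outer(idx, (seq_len(B) - 1) * nvox_in, `+`))
}

# ---- conv ------------------------------------------------------------------

new_conv <- function(gs_in, cin, cout, stride = 1, kernel = 3, pad = 1,
                     init_sd = NULL) {
  d <- length(gs_in)
  pgs <- gs_in + 2L * pad
  out_gs <- (gs_in + 2L * pad - kernel) %/% stride + 1L
  offs <- as.matrix(expand.grid(rep(list(seq_len(kernel) - 1), d)))
  vox_out <- grid_coords(out_gs)
  K <- nrow(offs)
  idx <- matrix(0L, prod(out_gs), K)
  for (k in seq_len(K)) {
    idx[, k] <- lin_index(sweep(vox_out * stride, 2, offs[k, ], `+`), pgs)
  }
  interior <- lin_index(grid_coords(gs_in) + pad, pgs)
  sd0 <- init_sd %||% sqrt(2 / (K * cin))
  list(
    type = "conv", gs_in = gs_in, gs_out = out_gs, cin = cin, cout = cout,
    K = K, npad = prod(pgs), nin = prod(gs_in), nout = prod(out_gs),
    idx = idx, interior = interior, batch_cache = new.env(parent = emptyenv()),
    params = list(W = matrix(rnorm(K * cin * cout, sd = sd0), cout, K * cin),
                  b = numeric(cout))
  )
}

conv_cols <- function(layer, B) {
  key <- as.character(B)
  env <- layer$batch_cache
  if (is.null(env[[key]])) {
    env[[key]] <- list(interior = batch_cols(layer$interior, layer$npad, B))
  }
  env[[key]]
}

conv_forward <- function(layer, X, B) {
  cc <- conv_cols(layer, B)
  P <- matrix(0, layer$cin, layer$npad * B)
  P[, cc$interior] <- X
  out <- conv_forward_cpp(P, layer$idx, layer$npad, B,
                          layer$params$W, layer$params$b)
  list(out = out, cache = list(P = P, B = B))
}

conv_backward <- function(layer, cache, dY) {
  cc <- conv_cols(layer, cache$B)
  r <- conv_backward_cpp(cache$P, layer$idx, layer$npad, cache$B,
                         layer$params$W, dY)
  list(dX = r$dP[, cc$interior, drop = FALSE],
       grads = list(W = r$dW, b = as.numeric(r$db)))
}

# ---- linear upsampling (factor 2) -----------------------------------------

new_upsample <- function(gs_in) {
  d <- length(gs_in)
  gs_out <- gs_in * 2L
  vox <- grid_coords(gs_out)
  src <- sweep(vox + 0.5, 2, rep(2, d), `/`) - 0.5
  for (ax in seq_len(d)) src[, ax] <- pmin(pmax(src[, ax], 0), gs_in[ax] - 1)
  lo <- floor(src)
  frac <- src - lo
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  idx <- matrix(0L, nrow(vox), nrow(corners))
  wts <- matrix(0, nrow(vox), nrow(corners))
  for (ci in seq_len(nrow(corners))) {
    pos <- lo
    w <- rep(1, nrow(vox))
    for (ax in seq_len(d)) {
      pos[, ax] <- pmin(lo[, ax] + corners[ci, ax], gs_in[ax] - 1)
      w <- w * if (corners[ci, ax] == 1) frac[, ax] else 1 - frac[, ax]
    }
    idx[, ci] <- lin_index(pos, gs_in)
    wts[, ci] <- w
  }
  list(type = "upsample", gs_in = gs_in, gs_out = gs_out,
       nin = prod(gs_in), nout = prod(gs_out), idx = idx, wts = wts,
       batch_cache = new.env(parent = emptyenv()), params = list())
}

upsample_forward <- function(layer, X, B) {
  list(out = upsample_forward_cpp(X, layer$idx, layer$wts, B, layer$nin),
       cache = list(B = B, nc = nrow(X)))
}

upsample_backward <- function(layer, cache, dY) {
  list(dX = upsample_backward_cpp(dY, layer$idx, layer$wts, cache$B, layer$nin),
       grads = list())
}

# ---- dense / reshape -------------------------------------------------------

new_dense <- function(n_in, n_out, init_sd = NULL) {
  sd0 <- init_sd %||% sqrt(2 / n_in)
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(rnorm(n_in * n_out, sd = sd0), n_in, n_out),
                     b = numeric(n_out)))
}

dense_forward <- function(layer, X, B) {
  list(out = sweep(X %*% layer$params$W, 2, layer$params$b, `+`),
       cache = list(X = X))
}

dense_backward <- function(layer, cache, dY) {
  list(dX = tcrossprod(dY, layer$params$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

# C x (voxels*B)  ->  B x (voxels*C)
new_flatten <- function(gs, channels) {
  list(type = "flatten", nvox = prod(gs), channels = channels, params = list())
}

flatten_forward <- function(layer, X, B) {
  a <- array(X, c(layer$channels, layer$nvox, B))
  list(out = matrix(aperm(a, c(3, 2, 1)), B, layer$nvox * layer$channels),
       cache = list(B = B))
}

flatten_backward <- function(layer, cache, dY) {
  B <- cache$B
  a <- array(dY, c(B, layer$nvox, layer$channels))
  list(dX = matrix(aperm(a, c(3, 2, 1)), layer$channels, layer$nvox * B),
       grads = list())
}

# B x (voxels*C)  ->  C x (voxels*B)
new_unflatten <- function(gs, channels) {
  list(type = "unflatten", nvox = prod(gs), channels = channels, params = list())
}

unflatten_forward <- function(layer, X, B) {
  a <- array(X, c(B, layer$nvox, layer$channels))
  list(out = matrix(aperm(a, c(3, 2, 1)), layer$channels, layer$nvox * B),
       cache = list(B = B))
}

unflatten_backward <- function(layer, cache, dY) {
  B <- cache$B
  a <- array(dY, c(layer$channels, layer$nvox, B))
  list(dX = matrix(aperm(a, c(3, 2, 1)), B, layer$nvox * layer$channels),
       grads = list())
}

# ---- activations -----------------------------------------------------------

new_relu <- function() list(type = "relu", params = list())
relu_forward <- function(layer, X, B) list(out = pmax(X, 0), cache = list(mask = X > 0))
relu_backward <- function(layer, cache, dY) list(dX = dY * cache$mask, grads = list())

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over channels (rows) of a C x N activation
softmax_cols <- function(X) {
  C <- nrow(X)
  mx <- X[1, ]
  for (j in seq_len(C)[-1]) mx <- pmax(mx, X[j, ])
  e <- exp(X - rep(mx, each = C))
  e / rep(colSums(e), each = C)
}

# ---- sequential plumbing ---------------------------------------------------

layer_forward <- function(layer, X, B) {
  switch(layer$type,
    conv = conv_forward(layer, X, B),
    upsample = upsample_forward(layer, X, B),
    dense = dense_forward(layer, X, B),
    flatten = flatten_forward(layer, X, B),
    unflatten = unflatten_forward(layer, X, B),
    relu = relu_forward(layer, X, B),
    stop("unknown layer type ", layer$type)
  )
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dY),
    upsample = upsample_backward(layer, cache, dY),
    dense = dense_backward(layer, cache, dY),
    flatten = flatten_backward(layer, cache, dY),
    unflatten = unflatten_backward(layer, cache, dY),
    relu = relu_backward(layer, cache, dY),
    stop("unknown layer type ", layer$type)
  )
}

seq_forward <- function(layers, X, B) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X, B)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

seq_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dY, grads = grads)
}

n_layer_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$params, length, integer(1))), numeric(1)))
}

# ---- template warp sampler (DAE / ADAE decode head) ------------------------
#
# Samples a fixed template (one-hot probabilities or intensities, stored
# C x voxels) at v + u(v), where u is the decoder's displacement output
# (d x voxels*B), optionally adding a decoded per-image intensity offset
# (1 x voxels*B) to the template before sampling. Returns the sampled
# channels and, on the backward pass, gradients with respect to the
# displacement (and offset). Gradients vanish where sampling positions are
# clamped at the grid border.

warp_sample <- function(template_mat, gs, field, B, offset = NULL) {
  d <- length(gs)
  nvox <- prod(gs)
  base <- t(grid_coords(gs))[, rep(seq_len(nvox), B), drop = FALSE]
  pts_raw <- base + field
  pts <- pts_raw
  inside <- matrix(TRUE, d, ncol(pts))
  for (ax in seq_len(d)) {
    inside[ax, ] <- pts_raw[ax, ] > 0 & pts_raw[ax, ] < gs[ax] - 1
    pts[ax, ] <- pmin(pmax(pts_raw[ax, ], 0), gs[ax] - 1)
  }
  lo <- floor(pts)
  for (ax in seq_len(d)) lo[ax, ] <- pmin(lo[ax, ], gs[ax] - 2)
  frac <- pts - lo
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  nC <- nrow(template_mat)
  out <- matrix(0, nC, ncol(pts))
  boff <- rep((seq_len(B) - 1) * nvox, each = nvox)
  info <- vector("list", nrow(corners))
  for (ci in seq_len(nrow(corners))) {
    w_ax <- matrix(0, d, ncol(pts))
    pos <- lo
    for (ax in seq_len(d)) {
      pos[ax, ] <- lo[ax, ] + corners[ci, ax]
      w_ax[ax, ] <- if (corners[ci, ax] == 1) frac[ax, ] else 1 - frac[ax, ]
    }
    w <- w_ax[1, ]
    for (ax in seq_len(d)[-1]) w <- w * w_ax[ax, ]
    lin <- lin_index(t(pos), gs)
    G <- gather_cols(template_mat, lin)
    if (!is.null(offset)) G <- G + gather_cols(offset, as.integer(lin + boff))
    out <- out + G * rep(w, each = nC)
    info[[ci]] <- list(w_ax = w_ax, w = w, lin = lin, G = G,
                       sign = ifelse(corners[ci, ] == 1, 1, -1))
  }
  list(out = out,
       cache = list(info = info, inside = inside, B = B, gs = gs,
                    nvox = nvox, boff = boff, has_offset = !is.null(offset),
                    nC = nC))
}

warp_sample_backward <- function(cache, dY) {
  d <- nrow(cache$inside)
  dF <- matrix(0, d, ncol(dY))
  dOff <- if (cache$has_offset) matrix(0, cache$nC, cache$nvox * cache$B) else NULL
  for (ci in seq_along(cache$info)) {
    inf <- cache$info[[ci]]
    s <- colSums(dY * inf$G)
    for (ax in seq_len(d)) {
      wo <- rep(1, ncol(dY))
      for (ax2 in seq_len(d)) if (ax2 != ax) wo <- wo * inf$w_ax[ax2, ]
      dF[ax, ] <- dF[ax, ] + s * wo * inf$sign[ax]
    }
    if (cache$has_offset) {
      scatter_add_cols_scaled(dOff, as.integer(inf$lin + cache$boff), dY, inf$w)
    }
  }
  dF <- dF * cache$inside
  list(dField = dF, dOffset = dOff)
}
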