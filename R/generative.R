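# The uniform generative contract: every model family implements encode,
# decode, reconstruct_item and sample_items, so the metric suite applies to
# statistical and network models unchanged. Items live in each model's
# native space (flattened landmark vectors for PCA shape models, label or
# intensity arrays for the networks); the distance function passed to the
# metrics decides how items are compared.

#' Encode an item into a model's latent space
#' @param model a fitted generative model.
#' @param x an item in the model's native input space.
#' @param ... passed to methods.
#' @return numeric latent vector.
#' @export
encode <- function(model, x, ...) UseMethod("encode")

#' Decode a latent vector into the model's output space
#' @param model a fitted generative model.
#' @param z numeric latent vector.
#' @param ... passed to methods.
#' @export
decode <- function(model, z, ...) UseMethod("decode")

#' Reconstruct an item (decode of its encoding)
#' @inheritParams encode
#' @export
reconstruct_item <- function(model, x, ...) UseMethod("reconstruct_item")

#' Draw new items from a model under the fairness sampling protocol
#'
#' Latents are drawn per dimension from the Normal described by the mean
#' and standard deviation of the training latents, then decoded.
#'
#' @param model a fitted generative model.
#' @param n number of items.
#' @param latent_stats list with `mean`/`sd`; default the model's stored
#'   training-latent statistics.
#' @param seed integer seed (sampling is deterministic per seed).
#' @param ... passed to methods.
#' @return list of n items.
#' @export
sample_items <- function(model, n, latent_stats = NULL, seed = 1, ...) {
  UseMethod("sample_items")
}

#' Latent dimensionality of a fitted model
#' @param model a fitted generative model.
#' @export
latent_dim <- function(model) UseMethod("latent_dim")

# ---- PCA shape model methods ----------------------------------------------

#' @export
encode.pca_shape_model <- function(model, x, ...) project(model, as.numeric(x))

#' @export
decode.pca_shape_model <- function(model, z, ...) reconstruct(model, z)

#' @export
reconstruct_item.pca_shape_model <- function(model, x, ...) {
  reconstruct(model, project(model, as.numeric(x)))
}

#' @export
sample_items.pca_shape_model <- function(model, n, latent_stats = NULL, seed = 1, ...) {
  S <- sample_ssm(model, n, latent_stats = latent_stats, seed = seed)
  lapply(seq_len(n), function(i) {
    v <- S[i, ]
    attr(v, "layout") <- model$layout
    attr(v, "d") <- model$d
    v
  })
}

#' @export
latent_dim.pca_shape_model <- function(model) model$p

# ---- appearance model methods ---------------------------------------------
# items are lists with fields `shape` and `appearance`

#' @export
encode.appearance_model <- function(model, x, ...) {
  c(project(model$shape_model, as.numeric(x$shape)),
    project(model$intensity_model, sam_normalize(model, x$shape, x$appearance)))
}

#' @export
reconstruct_item.appearance_model <- function(model, x, ...) {
  reconstruct_sam(model, x$shape, x$appearance)
}

#' @export
sample_items.appearance_model <- function(model, n, latent_stats = NULL, seed = 1, ...) {
  sample_sam(model, n, seed = seed)
}

#' @export
latent_dim.appearance_model <- function(model) {
  c(model$shape_model$p, model$intensity_model$p)
}
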