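# ggplot2 views of sweep and interpolation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep metric against training-set size
#'
#' Fold means per model with one-standard-error ribbons, on a log2 size
#' axis — the standard view for comparing generative model families as the
#' training set grows.
#'
#' @param object a [run_sweep()] result.
#' @param metric one of `"ga"`, `"specificity"`, `"likeness"`, `"las"`,
#'   `"normality_pct"`, `"missing_pct"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sweep_result <- function(object, metric = "ga", ...) {
  summ <- summarize_sweep(object)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_se")
  summ <- summ[!is.na(summ[[mcol]]), , drop = FALSE]
  lab <- c(ga = "generalization ability (ASSD)",
           specificity = "specificity (ASSD)",
           likeness = "likeness (DSI)", las = "latent ambiguity score",
           normality_pct = "non-normal latent dimensions [%]",
           missing_pct = "missing structures [%]")[metric]
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$size, y = .data[[mcol]],
                                     colour = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                      ymax = .data[[mcol]] + .data[[scol]],
                                      fill = .data$model),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(summ$size)) +
    ggplot2::labs(x = "training size N", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot interpolation distance profiles
#'
#' Distance of every decoded intermediate to both endpoints; smooth,
#' monotone crossing profiles indicate a continuous latent space.
#'
#' @param object an [interpolation_experiment()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.interpolation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles,
                              cols = c("dist_to_a", "dist_to_b"),
                              names_to = "endpoint", values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$distance,
                                     colour = .data$endpoint)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "interpolation parameter t", y = "distance") +
    ggplot2::theme_minimal()
}
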