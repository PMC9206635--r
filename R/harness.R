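# Experiment harness: training-set-size sweeps with the multi-fold schedule
# (four folds for N < 100, two folds for N >= 100, results averaged over
# folds), latent-space interpolation experiments, and report rendering.
# Each sweep cell is isolated: a failing fit marks the cell failed and the
# sweep continues; completed cells are written incrementally and are not
# recomputed when a sweep is resumed.

SWEEP_MODELS <- c("ssm", "lssm", "ae", "vae", "aegan", "dae")

#' Configure a training-set-size sweep
#'
#' @param population a [sample_population()] result; fold training subsets
#'   are drawn from its train split, metrics use its test split as the
#'   held-out / real reference set.
#' @param models model kinds to compare (subset of
#'   `ssm, lssm, ae, vae, aegan, dae`).
#' @param sizes increasing training-set sizes, each at most the population
#'   train-split size.
#' @param latent_dim network latent size (default 32).
#' @param epochs,batch_size network training schedule per cell.
#' @param variability_threshold PCA variability threshold (default 0.95).
#' @param seed global sweep seed; per-cell seeds are derived from it.
#' @param out_dir optional directory for incremental results
#'   (`sweep_results.csv`); enables resuming.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(population, models = c("ssm", "lssm", "ae", "vae", "dae"),
                         sizes = c(5, 10, 20, 40), latent_dim = 32,
                         epochs = 30, batch_size = 8,
                         variability_threshold = 0.95,
                         seed = 1, out_dir = NULL) {
  models <- match.arg(models, SWEEP_MODELS, several.ok = TRUE)
  sizes <- sort(as.integer(sizes))
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  if (max(sizes) > length(population$split$train)) {
    stop("sizes exceed the population's train split", call. = FALSE)
  }
  structure(
    list(population = population, models = models, sizes = sizes,
         latent_dim = latent_dim, epochs = epochs, batch_size = batch_size,
         variability_threshold = variability_threshold,
         seed = seed, out_dir = out_dir),
    class = "sweep_config"
  )
}

n_folds_for <- function(N) if (N < 100) 4L else 2L

# fit one model kind on the fold's training indices; returns the fitted
# model plus the item/distance adapters the metric suite needs
sweep_fit_model <- function(kind, config, idx, cell_seed) {
  pop <- config$population
  tpl <- pop$template
  gs <- tpl$grid_shape
  structures <- tpl$structure_order
  to_label <- function(x) {
    if (is.numeric(x) && is.null(dim(x))) {
      lbl <- attr(x, "label")
      if (!is.null(lbl)) return(lbl)
      landmarks_to_label(landmarks_unflatten(x, tpl$landmarks[, c("structure", "point_index")]),
                         gs, structures)
    } else x
  }
  # missing structures are reported separately (missing_pct); the adapter
  # silences assd's per-pair absence warnings to keep long sweeps readable
  dist_lab <- function(a, b) {
    suppressWarnings(assd(to_label(a), to_label(b), structures = structures))
  }
  if (kind %in% c("ssm", "lssm")) {
    shapes <- population_shapes(pop)[idx, , drop = FALSE]
    attr(shapes, "layout") <- tpl$landmarks[, c("structure", "point_index")]
    attr(shapes, "d") <- length(gs)
    model <- if (kind == "ssm") {
      fit_ssm(shapes, config$variability_threshold)
    } else {
      fit_lssm(shapes, variability_threshold = config$variability_threshold)
    }
    ho_shapes <- population_shapes(pop, "test")
    held_out <- lapply(seq_len(nrow(ho_shapes)), function(i) {
      v <- ho_shapes[i, ]
      attr(v, "layout") <- tpl$landmarks[, c("structure", "point_index")]
      attr(v, "d") <- length(gs)
      attr(v, "label") <- pop$instances[[pop$split$test[i]]]$label %||%
        landmarks_to_label(landmarks_unflatten(v, attr(v, "layout")), gs, structures)
      v
    })
  } else {
    spec <- network_spec(kind, gs, in_channels = length(structures) + 1,
                         latent_dim = config$latent_dim, data_mode = "label",
                         seed = cell_seed)
    model <- build_network(spec)
    model <- train(model, population_labels(pop, idx),
                   train_config(epochs = config$epochs,
                                batch_size = config$batch_size,
                                seed = cell_seed))
    held_out <- population_labels(pop, "test")
  }
  list(model = model, held_out = held_out, dist = dist_lab,
       to_label = to_label, structures = structures)
}

sweep_cell_metrics <- function(fitted, cell_seed) {
  model <- fitted$model
  held_out <- fitted$held_out
  n_ref <- length(held_out)
  ga <- generalization_ability(model, held_out, fitted$dist)
  # one sampled set (N_S = N_R, fairness protocol) serves specificity,
  # likeness and the missing-structure fraction; rasterize each sample once
  synth <- lapply(sample_items(model, n_ref, seed = cell_seed), function(s) {
    if (is.numeric(s) && is.null(dim(s))) attr(s, "label") <- fitted$to_label(s)
    s
  })
  spec <- mean(vapply(synth, function(s) {
    min(vapply(held_out, function(r) fitted$dist(r, s), numeric(1)))
  }, numeric(1)))
  dsi <- likeness_dsi(held_out, synth, fitted$dist)
  las <- latent_ambiguity_score(model, held_out)
  norm_pct <- if (n_ref >= 8) {
    lat <- do.call(rbind, lapply(held_out, function(r) as.numeric(encode(model, r))))
    suppressWarnings(as.numeric(normality_fraction(lat)))
  } else NA_real_ # Shapiro-Wilk needs at least 8 reference items
  comp <- compactness(model)
  miss <- mean(vapply(synth, function(s) {
    missing_structures(fitted$to_label(s), fitted$structures)
  }, numeric(1)))
  tibble::tibble(
    ga = ga, specificity = spec, likeness = dsi, las = las,
    normality_pct = norm_pct, compactness = format_compactness(comp),
    compactness_total = sum(comp), missing_pct = 100 * miss
  )
}

#' Run a training-set-size sweep over several model families
#'
#' For each (model, size) cell the fold schedule is applied (four folds for
#' `N < 100`, two for `N >= 100`); each fold draws a seeded training subset
#' without replacement from the population's train split, fits the model,
#' and evaluates generalization ability, specificity, likeness, LAS,
#' latent normality, compactness and the missing-structure percentage on
#' the population's held-out test split (ASSD distance for label outputs).
#' Failed cells are recorded with `status = "failed"` and the sweep
#' continues. With `out_dir` set, every completed row is appended to
#' `sweep_results.csv` and re-running the same config skips completed
#' cells.
#'
#' @param config a [sweep_config()].
#' @return tibble of class `sweep_result`: one row per (model, size, fold)
#'   plus the metric columns.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  csv_path <- if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(config$out_dir, "sweep_results.csv")
  }
  done <- NULL
  if (!is.null(csv_path) && file.exists(csv_path)) {
    done <- readr::read_csv(csv_path, show_col_types = FALSE)
  }
  rows <- list()
  for (kind in config$models) {
    for (N in config$sizes) {
      for (fold in seq_len(n_folds_for(N))) {
        if (!is.null(done) &&
            nrow(dplyr::filter(done, .data$model == kind, .data$size == N,
                               .data$fold == !!fold)) > 0) {
          rows[[length(rows) + 1]] <- dplyr::filter(
            done, .data$model == kind, .data$size == N, .data$fold == !!fold)
          next
        }
        cell_seed <- child_seed(config$seed,
                                match(kind, SWEEP_MODELS) * 1000 + N * 10 + fold)
        idx <- with_seed(cell_seed, {
          config$population$split$train[
            sample.int(length(config$population$split$train), N)]
        })
        t0 <- proc.time()[3]
        row <- tryCatch({
          fitted <- sweep_fit_model(kind, config, idx, cell_seed)
          m <- sweep_cell_metrics(fitted, cell_seed)
          dplyr::bind_cols(
            tibble::tibble(model = kind, size = N, fold = fold,
                           status = "ok"),
            m,
            tibble::tibble(seconds = proc.time()[3] - t0)
          )
        }, error = function(e) {
          warning("sweep cell (", kind, ", N=", N, ", fold ", fold,
                  ") failed: ", conditionMessage(e))
          tibble::tibble(model = kind, size = N, fold = fold,
                         status = "failed",
                         ga = NA_real_, specificity = NA_real_,
                         likeness = NA_real_, las = NA_real_,
                         normality_pct = NA_real_,
                         compactness = NA_character_,
                         compactness_total = NA_real_,
                         missing_pct = NA_real_,
                         seconds = proc.time()[3] - t0)
        })
        rows[[length(rows) + 1]] <- row
        if (!is.null(csv_path)) {
          readr::write_csv(row, csv_path, append = file.exists(csv_path))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Average a sweep result over folds
#'
#' @param result a [run_sweep()] result.
#' @return tibble with one row per (model, size): fold means and the
#'   between-fold standard error of each numeric metric.
#' @export
summarize_sweep <- function(result) {
  result |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$model, .data$size) |>
    dplyr::summarise(
      dplyr::across(c("ga", "specificity", "likeness", "las",
                      "normality_pct", "missing_pct"),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         se = ~ stats::sd(.x, na.rm = TRUE) /
                           sqrt(max(1, sum(!is.na(.x)))))),
      compactness = dplyr::first(.data$compactness),
      folds = dplyr::n(),
      .groups = "drop"
    )
}

# ---- interpolation ---------------------------------------------------------

#' Latent-space interpolation between two items
#'
#' Projects both items, decodes `steps` equally spaced points on the linear
#' segment `z_t = (1 - t) f(a) + t f(b)`, and records the distance of each
#' decoding to both endpoints. Smooth, gradual profiles indicate a
#' well-behaved latent space; abrupt jumps reveal holes.
#'
#' @param model a fitted generative model.
#' @param a,b items in the model's native space.
#' @param steps number of interpolation steps (default 20; >= 2).
#' @param dist distance function between decoded items and endpoints.
#' @return object of class `interpolation_result`: list with `profiles`
#'   (tibble: `step`, `t`, `dist_to_a`, `dist_to_b`) and `decodings`.
#' @export
interpolation_experiment <- function(model, a, b, steps = 20, dist) {
  stopifnot(steps >= 2)
  za <- as.numeric(encode(model, a))
  zb <- as.numeric(encode(model, b))
  ts <- seq(0, 1, length.out = steps)
  decodings <- lapply(ts, function(t) decode(model, (1 - t) * za + t * zb))
  profiles <- tibble::tibble(
    step = seq_len(steps), t = ts,
    dist_to_a = vapply(decodings, function(x) dist(x, a), numeric(1)),
    dist_to_b = vapply(decodings, function(x) dist(x, b), numeric(1))
  )
  structure(list(profiles = profiles, decodings = decodings,
                 endpoints = list(a = a, b = b)),
            class = "interpolation_result")
}

# ---- reporting -------------------------------------------------------------

#' Render sweep results to CSV, JSON summary and figures
#'
#' Writes `sweep_results.csv` (one row per cell), `summary.json` (fold
#' means per model and size) and one figure per metric (metric vs training
#' size per model, plus a missing-structure bar chart). Rendering from the
#' same results is deterministic.
#'
#' @param reports a [run_sweep()] result.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
render_report <- function(reports, out_dir) {
  if (nrow(reports) == 0) stop("no reports to render", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  csv <- file.path(out_dir, "sweep_results.csv")
  readr::write_csv(reports, csv)
  paths <- c(paths, csv)
  summ <- summarize_sweep(reports)
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, js, digits = 10, pretty = TRUE)
  paths <- c(paths, js)
  for (metric in c("ga", "specificity", "likeness", "las", "normality_pct")) {
    p <- autoplot.sweep_result(reports, metric = metric)
    f <- file.path(out_dir, paste0(metric, "_vs_size.png"))
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
    paths <- c(paths, f)
  }
  pm <- summ |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$size), y = .data$missing_pct_mean,
                                 fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "training size N", y = "missing structures [%]",
                  title = "Non-generated structures") +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, "missing_structures.png")
  ggplot2::ggsave(f, pm, width = 6, height = 4, dpi = 120)
  paths <- c(paths, f)
  invisible(paths)
}
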