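# Population export/import. Labels and appearances go to PNG (2D; label
# values are stored as gray levels value/255) or NIfTI (3D); landmarks to
# per-instance CSV tables; seeds, amplitudes and splits to metadata JSON.

write_image_2d <- function(img, path, label = FALSE) {
  # PNG rows are the y axis; our arrays are (x, y)
  m <- t(if (label) img / 255 else pmin(pmax(img, 0), 1))
  png::writePNG(m, target = path)
}

read_image_2d <- function(path, label = FALSE) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  img <- t(m)
  if (label) array(as.integer(round(img * 255)), dim(img)) else img
}

#' Write a population to a directory
#'
#' Layout: `template_landmarks.csv`, `template_label.(png|nii.gz)`,
#' `template_appearance.(png|nii.gz)`, per-instance
#' `landmarks_%04d.csv` / `label_%04d` / `appearance_%04d`, and
#' `metadata.json` (kind, seed, k, amplitudes, smoothness, grid shape,
#' offset scale, splits). Landmark CSVs have columns `structure`,
#' `point_index`, `x`, `y`\[, `z`\].
#'
#' @param population a [sample_population()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- population$template
  d <- length(tpl$grid_shape)
  is2d <- d == 2
  ext <- if (is2d) ".png" else ".nii.gz"
  wimg <- function(img, path, label = FALSE) {
    if (is2d) {
      write_image_2d(img, path, label)
    } else {
      RNifti::writeNifti(RNifti::asNifti(img * 1.0), path)
    }
  }
  readr::write_csv(tpl$landmarks, file.path(dir, "template_landmarks.csv"))
  wimg(tpl$label, file.path(dir, paste0("template_label", ext)), label = TRUE)
  wimg(tpl$appearance, file.path(dir, paste0("template_appearance", ext)))
  for (i in seq_along(population$instances)) {
    inst <- population$instances[[i]]
    readr::write_csv(inst$landmarks, file.path(dir, sprintf("landmarks_%04d.csv", i)))
    if (!is.null(inst$label)) {
      wimg(inst$label, file.path(dir, sprintf("label_%04d%s", i, ext)), label = TRUE)
    }
    if (!is.null(inst$appearance)) {
      wimg(inst$appearance, file.path(dir, sprintf("appearance_%04d%s", i, ext)))
    }
  }
  meta <- list(
    kind = tpl$kind, seed = population$seed, n = length(population$instances),
    grid_shape = tpl$grid_shape, k = population$basis$k,
    amplitudes = population$basis$amplitudes,
    smoothness = population$basis$smoothness,
    offset_scale = population$offset_scale,
    structure_names = tpl$structure_names,
    split = population$split
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a population directory written by [write_population()]
#'
#' Restores landmarks, label and appearance images, the template and the
#' split metadata (the deformation basis itself is not serialized; its
#' parameters are available in the metadata).
#'
#' @param dir directory path.
#' @return list with `instances`, `template` fields and `split`, of class
#'   `shape_population` (without `basis`).
#' @export
read_population <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  d <- length(meta$grid_shape)
  is2d <- d == 2
  ext <- if (is2d) ".png" else ".nii.gz"
  rimg <- function(path, label = FALSE) {
    if (is2d) {
      read_image_2d(path, label)
    } else {
      img <- as.array(RNifti::readNifti(path))
      if (label) array(as.integer(round(img)), dim(img)) else img
    }
  }
  tpl <- list(
    kind = meta$kind, grid_shape = as.integer(meta$grid_shape), seed = meta$seed,
    landmarks = readr::read_csv(file.path(dir, "template_landmarks.csv"),
                                show_col_types = FALSE),
    label = rimg(file.path(dir, paste0("template_label", ext)), label = TRUE),
    appearance = rimg(file.path(dir, paste0("template_appearance", ext))),
    structure_names = meta$structure_names,
    structure_order = seq_along(meta$structure_names)
  )
  class(tpl) <- "shape_template"
  instances <- lapply(seq_len(meta$n), function(i) {
    lab_path <- file.path(dir, sprintf("label_%04d%s", i, ext))
    app_path <- file.path(dir, sprintf("appearance_%04d%s", i, ext))
    structure(
      list(
        landmarks = readr::read_csv(file.path(dir, sprintf("landmarks_%04d.csv", i)),
                                    show_col_types = FALSE),
        label = if (file.exists(lab_path)) rimg(lab_path, label = TRUE),
        appearance = if (file.exists(app_path)) rimg(app_path),
        true_coefficients = NULL, true_intensity_offset = NULL
      ),
      class = "shape_instance"
    )
  })
  structure(
    list(instances = instances, template = tpl, basis = NULL,
         split = lapply(meta$split, as.integer), seed = meta$seed,
         offset_scale = meta$offset_scale),
    class = "shape_population"
  )
}
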