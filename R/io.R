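#' Read and write scene artifacts
#'
#' Videos are written as multi-page TIFF (lossless; one page per frame, NIR
#' and white-light as separate files), annotations as JSON with 0-based
#' pixel coordinates (x right, y down) and half-open 0-based grid-module
#' intervals, configurations as YAML, datasets as CSV with a JSON split
#' manifest.
#'
#' @param scene An `icgfa_scene`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return `write_scene()` invisibly returns the written paths.
#' @name icgfa_io
NULL

#' @rdname icgfa_io
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- function(a) {
    d <- dim(a)
    lapply(seq_len(d[3]), function(t) a[, , t] / 255)
  }
  paths <- c(
    nir = file.path(dir, paste0(stem, "_nir.tif")),
    white = file.path(dir, paste0(stem, "_white.tif")),
    annotation = file.path(dir, paste0(stem, "_annotation.json")),
    config = file.path(dir, paste0(stem, "_config.yaml"))
  )
  tiff::writeTIFF(norm(scene$nir), paths["nir"], bits.per.sample = 8)
  tiff::writeTIFF(norm(scene$white), paths["white"], bits.per.sample = 8)
  write_annotation(scene$annotation, paths["annotation"])
  cfg <- scene$config
  cfg$zone_params <- lapply(cfg$zone_params, lapply, as.numeric)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}

#' @rdname icgfa_io
#' @param annotation An `icgfa_annotation`.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  a <- annotation
  obj <- list(
    line = data.frame(x = a$line$x - 1, y = a$line$y - 1),  # 0-based pixels
    cols = a$cols - 1,
    labels = as.character(a$labels),
    stapler_band = if (is.null(a$stapler_band)) NULL else a$stapler_band - 1L,
    stapler_center = if (is.na(a$stapler_center)) NULL else a$stapler_center - 1,
    line_row = a$line_row - 1
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname icgfa_io
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    line = tibble::tibble(x = obj$line$x + 1, y = obj$line$y + 1),
    cols = as.integer(obj$cols + 1),
    labels = zone_factor(obj$labels),
    stapler_band = if (is.null(obj$stapler_band)) NULL else as.integer(obj$stapler_band + 1),
    stapler_center = if (is.null(obj$stapler_center)) NA_real_ else obj$stapler_center + 1,
    line_row = obj$line_row + 1
  ), class = "icgfa_annotation")
}

#' @rdname icgfa_io
#' @param dataset An `icgfa_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(dataset), path)
  manifest <- lapply(base::split(dataset$video_id, dataset$split), function(v)
    sort(unique(v)))
  jsonlite::write_json(manifest, paste0(tools::file_path_sans_ext(path), "_splits.json"),
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname icgfa_io
#' @export
read_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  d$label <- zone_factor(d$label)
  attr(d, "class_counts") <- table(d$label)
  class(d) <- c("icgfa_dataset", class(d))
  d
}

#' Save or load a trained model as JSON
#'
#' Model weights and metadata are serialised to a single JSON file (numbers
#' at full precision), portable across platforms.
#'
#' @param model An `icgfa_knn` or `icgfa_bilstm`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  ser <- function(x) {
    if (is.matrix(x)) list(.matrix = dim(x), data = as.numeric(x))
    else if (is.list(x) && !is.data.frame(x)) lapply(x, ser)
    else x
  }
  obj <- list(class = class(model)[1])
  if (inherits(model, "icgfa_bilstm")) {
    obj$params <- ser(model$params)
    obj$hidden_units <- model$hidden_units
    obj$classes <- model$classes
    obj$class_weights <- model$class_weights
    obj$stop_epoch <- model$stop_epoch
    obj$best_epoch <- model$best_epoch
    obj$config <- model$config
  } else if (inherits(model, "icgfa_knn")) {
    obj$X <- ser(model$X); obj$y <- as.character(model$y)
    obj$k <- model$k; obj$cv_accuracy <- model$cv_accuracy
  } else abort("unsupported model type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  deser <- function(x) {
    if (is.list(x) && !is.null(x$.matrix))
      matrix(x$data, x$.matrix[1], x$.matrix[2])
    else if (is.list(x)) lapply(x, deser)
    else x
  }
  if (obj$class == "icgfa_bilstm") {
    structure(list(params = deser(obj$params), hidden_units = obj$hidden_units,
                   classes = obj$classes, class_weights = obj$class_weights,
                   layers = c("sequence input", "bi-LSTM", "fully connected",
                              "soft-max", "classification output"),
                   log = NULL, stop_epoch = obj$stop_epoch,
                   best_epoch = obj$best_epoch, best_val_loss = NA_real_,
                   config = obj$config),
              class = "icgfa_bilstm")
  } else if (obj$class == "icgfa_knn") {
    structure(list(X = deser(obj$X), y = zone_factor(obj$y), k = obj$k,
                   weighting = "inverse_distance", cv_report = NULL,
                   cv_accuracy = obj$cv_accuracy),
              class = "icgfa_knn")
  } else abort("unknown model class in checkpoint")
}
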