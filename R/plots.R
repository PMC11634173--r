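#' Plot a feature grid as a raster map
#'
#' @param object An `icgfa_features`.
#' @param feature Which milestone to map.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icgfa_features <- function(object, feature = "i_max", ...) {
  d <- as_tibble(object)
  d <- d[d$valid, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data[[feature]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = feature) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "grid column", y = "grid row",
                  title = sprintf("%s over the %dx%d grid", feature,
                                  object$grid_shape[1], object$grid_shape[2])) +
    ggplot2::theme_minimal()
}

#' Plot predicted and true labels along a line
#'
#' Shows the per-coordinate zone classes of a line sample in the in-theatre
#' colour convention (red good, green expert, blue poor), with the truth
#' track underneath when present.
#'
#' @param sample A line-sample tibble with `position` and `label` (and
#'   optionally `truth`).
#' @return A ggplot.
#' @export
plot_line_labels <- function(sample) {
  d <- tibble::tibble(position = sample$position,
                      label = as.character(sample$label), track = "predicted")
  if (!is.null(sample$truth))
    d <- dplyr::bind_rows(d, tibble::tibble(position = sample$position,
                                            label = as.character(sample$truth),
                                            track = "truth"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$track,
                                  fill = .data$label)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(good = "#d73027", expert = "#1a9850",
                                          poor = "#4575b4")) +
    ggplot2::labs(x = "line coordinate (grid modules, proximal to distal)",
                  y = NULL, fill = "zone") +
    ggplot2::theme_minimal()
}

#' Plot the training curve of a sequence model
#'
#' @param object An `icgfa_bilstm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icgfa_bilstm <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = "bi-LSTM training", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot evaluation metrics
#'
#' @param object An `icgfa_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icgfa_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#1a9850") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Expert-zone prediction metrics") +
    ggplot2::theme_minimal()
}
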