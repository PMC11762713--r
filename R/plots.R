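# ggplot2 helpers for phantoms, uncertainty maps and training histories

pixel_tibble <- function(m, value = "value") {
  tb <- tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                       col = rep(seq_len(ncol(m)), each = nrow(m)),
                       value = as.numeric(m))
  names(tb)[3] <- value
  tb
}

#' Plot a single intensity or mask grid
#'
#' @param m Numeric matrix.
#' @param title Plot title.
#' @return A ggplot object (rows increase downward, as in image display).
#' @export
plot_grid_map <- function(m, title = NULL) {
  ggplot2::ggplot(pixel_tibble(m),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phantom <- function(object, ...) {
  tb <- pixel_tibble(object$image)
  edge <- tibble::tibble(row = seq_len(object$spec$height),
                         col = object$boundary_col,
                         clarity = object$clarity)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = edge[!is.na(edge$col), ],
                       ggplot2::aes(color = .data$clarity), linewidth = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "phantom mammogram", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.uncertainty_estimate <- function(object, ...) {
  maps <- list("pixel entropy" = object$pi_pixel,
               "top-hat" = object$tophat,
               "shock-filtered" = object$cesf,
               "boundary" = object$boundary)
  tb <- dplyr::bind_rows(lapply(names(maps), function(nm) {
    dplyr::mutate(pixel_tibble(maps[[nm]]), stage = nm)
  }))
  tb$stage <- factor(tb$stage, levels = names(maps))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~stage, nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.train_state <- function(object, ...) {
  tb <- tidyr::pivot_longer(object$history,
                            cols = c("sup_loss", "con_loss", "val_loss"),
                            names_to = "loss", values_to = "value")
  tb <- tb[!is.na(tb$value), ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste("training:", object$regime %||% "untrained"),
                  y = "loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pectseg_experiment <- function(object, ...) {
  tb <- tidyr::pivot_longer(object$comparison,
                            cols = c("mean_dice", "mean_iou",
                                     "mean_hausdorff"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$regime, y = .data$value,
                                   fill = .data$regime)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
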