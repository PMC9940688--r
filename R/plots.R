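# ggplot2 presentation layer.

.raster_df <- function(m) {
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
}

#' Plot an importance map as a heat raster
#' @param object an [importance_map()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot importance_map
#' @export
autoplot.importance_map <- function(object, ...) {
  df <- .raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "importance") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Importance map (", object$source, ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a key-region image (masked pixels black)
#' @param object a `key_region_image`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot key_region_image
#' @export
autoplot.key_region_image <- function(object, ...) {
  img <- object$image
  df <- .raster_df(img[, , 1L])
  df$fill <- grDevices::rgb(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
                            as.vector(img[, , 3L]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Key region (kept %.1f%%)",
                                  100 * object$kept_fraction),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class metrics of a classification report
#' @param object a [classification_report()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tidyr_longer_metrics(object$per_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "percent", x = NULL,
                  title = sprintf("Macro F1 %.1f / Acc %.1f",
                                  object$f1, object$accuracy)) +
    ggplot2::theme_minimal()
}

# small local pivot so the package does not need tidyr for one call
tidyr_longer_metrics <- function(per_class) {
  dplyr::bind_rows(lapply(c("precision", "recall", "f1"), function(m)
    tibble::tibble(class = per_class$class, metric = m,
                   value = per_class[[m]])))
}
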