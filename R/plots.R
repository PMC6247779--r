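#' Plot methods for analysis results
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: per-kind drive of a cell, the class spectrum of its input, a
#' theme map, and peak-normalized signature histograms.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name retcouple-autoplot
NULL

#' @rdname retcouple-autoplot
#' @method autoplot drive_table
#' @export
autoplot.drive_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$kind <- factor(df$kind, levels = df$kind)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(
      title = paste0("Synaptic and coupling drive of ",
                     attr(object, "cell_id")),
      subtitle = sprintf("arbor fraction %.2f", attr(object, "arbor_fraction")),
      x = NULL, y = "contacts in volume") +
    ggplot2::theme_minimal()
}

#' @rdname retcouple-autoplot
#' @method autoplot input_spectrum
#' @export
autoplot.input_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class_label <- factor(df$class_label, levels = rev(df$class_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                   y = .data$class_label)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "share of input", y = NULL,
                  title = "Presynaptic class spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname retcouple-autoplot
#' @method autoplot theme_map
#' @export
autoplot.theme_map <- function(object, ...) {
  lab <- object$labels
  df <- tidyr::expand_grid(row = seq_len(nrow(lab)),
                           col = seq_len(ncol(lab)))
  df$label <- factor(lab[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Theme map (k = %d)", object$k),
                  x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_void()
}

#' @rdname retcouple-autoplot
#' @method autoplot signature_histogram
#' @export
autoplot.signature_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pv, y = .data$normalized)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "pixel value (PV)", y = "peak-normalized N",
                  title = "Signature histogram") +
    ggplot2::theme_minimal()
}

#' @rdname retcouple-autoplot
#' @param census A [coupling_census()] result.
#' @export
plot_coupling_matrix <- function(census, ...) {
  stopifnot(inherits(census, "coupling_census"))
  df <- census$superclass_pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$superclass_a,
                                   y = .data$superclass_b,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Gap-junction coupling census") +
    ggplot2::theme_minimal()
}
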