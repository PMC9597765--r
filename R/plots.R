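#' Layer accuracy profile plot
#'
#' Mean cross-validated accuracy per layer with standard-deviation bars,
#' one line per feature type / color mode combination, plus the dummy
#' baseline if given.
#'
#' @param results One or more `layer_probe_results` tibbles (row-bound).
#' @param dummy Optional baseline accuracy drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_layer_accuracy <- function(results, dummy = NULL) {
  df <- dplyr::mutate(tibble::as_tibble(results),
                      series = paste(.data$feature_type, .data$color_mode))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_index,
                                        y = .data$mean_accuracy,
                                        color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                                        ymax = .data$mean_accuracy + .data$sd_accuracy),
                           width = 0.2) +
    ggplot2::scale_x_continuous(breaks = unique(df$depth_index)) +
    ggplot2::labs(x = "layer depth index", y = "mean CV accuracy",
                  color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(dummy))
    p <- p + ggplot2::geom_hline(yintercept = dummy, linetype = "dashed")
  p
}

#' @export
autoplot.layer_probe_results <- function(object, ...) {
  plot_layer_accuracy(object, ...)
}

#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a two-component Gram PCA
#' @param scatter Output of [gram_pca_scatter()].
#' @return A ggplot object.
#' @export
plot_gram_scatter <- function(scatter) {
  ev <- attr(scatter, "explained_variance")
  lab <- function(i) {
    if (!is.null(ev) && length(ev) >= i)
      sprintf("PC%d (%.1f%%)", i, 100 * ev[i]) else paste0("PC", i)
  }
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        color = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2), color = NULL) +
    ggplot2::theme_minimal()
}
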