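#' Plot a feature-count versus accuracy sweep
#'
#' @param object a [sweep_dimension()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kta_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$dim,
                                             y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimum, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "number of selected features",
                  y = sprintf("%s accuracy (%%)", object$cv_scheme),
                  title = sprintf("optimum: %d features (%.1f%%)",
                                  object$optimum, object$max_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot KTA feature weights
#'
#' @param object a [kta_rank_features()] result.
#' @param top how many top-ranked features to show (default 20).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kta_ranking <- function(object, top = 20, ...) {
  d <- head(object$ranking, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "KTA weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of samples on the first two principal components
#'
#' @param data data frame with features and a label column.
#' @param features feature columns to project.
#' @param label_col grouping column for colour (default `"label"`).
#' @return a ggplot object.
#' @export
plot_pca_groups <- function(data, features, label_col = "label") {
  pc <- pca_project(data, features)
  ev <- attr(pc, "explained_var")
  pc$group <- data[[label_col]]
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * ev[2]),
                  colour = label_col) +
    ggplot2::theme_minimal()
}

#' Heatmap of a phase-synchronization connectivity matrix
#'
#' @param object a [connectivity_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  g <- object$gamma_vals
  d <- expand.grid(x = rownames(g), y = colnames(g),
                   stringsAsFactors = FALSE)
  d$gamma <- as.vector(g)
  d$x <- factor(d$x, levels = rownames(g))
  d$y <- factor(d$y, levels = rev(colnames(g)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$gamma)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(Gamma)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("band %s (%g-%g Hz)",
                                  object$band$name %||% "",
                                  object$band$lo, object$band$hi)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
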