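#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Profile heatmap with clustered axes
#'
#' The heatmap view of the kinetic feature matrix: lines on the y-axis,
#' features on the x-axis, tile fill the log2 fold change, both axes
#' ordered by their dendrogram leaf orders.
#'
#' @param data Feature matrix from [build_feature_matrix()].
#' @param row_dendro,col_dendro Optional `pheno_dendro` objects; computed
#'   with defaults when missing.
#' @param log2 Show log2 folds.
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(data, row_dendro = NULL, col_dendro = NULL,
                                 log2 = TRUE) {
  assert_feature_table(data)
  row_dendro <- row_dendro %||% hierarchical_cluster(data, "lines")
  col_dendro <- col_dendro %||% hierarchical_cluster(data, "probes")
  long <- tidyr::pivot_longer(data, cols = tidyselect::all_of(
    feature_columns(data)), names_to = "feature", values_to = "fold")
  long$value <- if (log2) base::log2(long$fold) else long$fold
  long$line_id <- factor(long$line_id,
                         levels = row_dendro$labels[row_dendro$leaf_order])
  long$feature <- factor(long$feature,
                         levels = col_dendro$labels[col_dendro$leaf_order])
  ggplot2::ggplot(long, ggplot2::aes(.data$feature, .data$line_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = if (log2) "log2 fold" else "fold") +
    ggplot2::labs(x = "probe feature", y = "cell line") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @method autoplot pheno_scores
#' @export
autoplot.pheno_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$top_score, .data$second_score,
                               colour = .data$origin,
                               shape = .data$origin == .data$predicted)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                name = "correct") +
    ggplot2::labs(x = "highest LDA score", y = "2nd highest LDA score",
                  colour = "origin") +
    ggplot2::theme_bw()
}

#' @method autoplot pheno_jackknife
#' @export
autoplot.pheno_jackknife <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$predicted, .data$true,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(x = "predicted origin", y = "true origin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot pheno_stepwise
#' @export
autoplot.pheno_stepwise <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(.data$step, .data$lambda,
                                   colour = .data$action)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "step", y = "Wilks' lambda") +
    ggplot2::theme_bw()
}
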