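#' Stacked-bar plot of cell-type composition per sample
#'
#' @param composition Long composition table from [compute_proportions()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  assert_columns(composition, c("sample_id", "cell_type", "proportion"),
                 "composition")
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proportion of cells", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked-bar plot of sporadic vs sustained cell fractions per time point
#'
#' @param fractions Output of [persistence_fractions()] or
#'   [post_vaccination_fractions()] (the latter via its `class_label`).
#' @return A ggplot object.
#' @export
plot_persistence <- function(fractions) {
  fill_col <- if ("class_label" %in% names(fractions)) "class_label" else "category"
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = factor(.data$time_point), y = .data$fraction,
                               fill = .data[[fill_col]])) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$individual)) +
    ggplot2::labs(x = "Day", y = "Fraction of keyed cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a clonotype trajectory
#'
#' Frequency of the traced clonotype among keyed cells of its receptor class
#' across the time series, one line per individual.
#'
#' @param object A `clonotype_trajectory` from [trace_clonotype()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clonotype_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$time_point, y = .data$frequency,
                               colour = .data$individual)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste0(object$receptor_class, " clonotype trajectory"),
                  subtitle = object$key,
                  x = "Day", y = "Frequency among keyed cells") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.clonotype_trajectory
#' @param trajectory A `clonotype_trajectory`.
#' @export
plot_trajectory <- function(trajectory) autoplot.clonotype_trajectory(trajectory)

#' Heatmap-style tile plot of V-gene usage across samples
#'
#' @param usage Long usage table from [v_gene_usage()].
#' @return A ggplot object.
#' @export
plot_v_gene_usage <- function(usage) {
  ggplot2::ggplot(usage, ggplot2::aes(x = .data$v_gene, y = .data$sample_id,
                                      fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "V gene", y = NULL, fill = "Frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Shannon diversity over time per sample
#'
#' @param diversity Output of [shannon_diversity()].
#' @return A ggplot object.
#' @export
plot_shannon_diversity <- function(diversity) {
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = .data$time_point, y = .data$h,
                               colour = .data$individual)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Day", y = "Shannon index (nats)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
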