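#' Plot a tetraloop census
#'
#' Bar chart of type I-E tetraloop counts per strain, faceted by
#' canonical/orphan context.
#'
#' @param census tibble from [tetraloop_census()].
#' @return a ggplot.
#' @export
plot_tetraloop_census <- function(census) {
  ggplot2::ggplot(census,
                  ggplot2::aes(x = .data$strain_id, y = .data$n,
                               fill = .data$tetraloop)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~context) +
    ggplot2::labs(x = NULL, y = "type I-E arrays", fill = "tetraloop") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of shared spacer counts
#'
#' @param object a `sharing_summary` from [sharing_matrix()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.sharing_summary <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$target_strain,
                               y = .data$query_strain,
                               fill = .data$n_shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_shared)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "target strain", y = "query strain",
                  fill = sprintf(">= %.0f%% shared", 100 * object$min_identity)) +
    ggplot2::theme_minimal()
}

#' Spacer counts per array class
#'
#' @param arrays labeled array tibble (`subtype`, `context`, `n_spacers`).
#' @return a ggplot.
#' @export
plot_array_sizes <- function(arrays) {
  type <- if ("subtype" %in% names(arrays)) arrays$subtype else arrays$system_type
  d <- tibble(class = ifelse(type == "I-E",
                             paste("I-E", arrays$context), type),
              n_spacers = arrays$n_spacers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n_spacers)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "spacers per array") +
    ggplot2::theme_minimal()
}
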