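#' Plot the baseline distribution of a permutation test
#'
#' Histogram of the permuted statistic values with the observed value
#' marked; the classic single-system baseline picture.
#'
#' @param object A [kin_permtest()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_permtest
#' @export
autoplot.kin_permtest <- function(object, ...) {
  df <- tibble::tibble(value = object$baseline)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = object$statistic, y = "permutations",
      title = sprintf("observed = %.3f, z = %.2f (%s)",
                      object$observed, object$z, object$classification)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of corpus z-scores
#'
#' @param results A tibble from [predictive_structure()] or
#'   [compositionality()].
#' @param threshold Significance threshold drawn as dashed lines.
#' @return A ggplot object: z-score histogram, significant systems
#'   highlighted.
#' @export
plot_z_distribution <- function(results, threshold = 1.96) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$z,
                               fill = .data$classification != "not_significant")) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-threshold, 0, threshold),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("grey40", "black", "grey40")) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "z-score", y = "systems") +
    ggplot2::theme_minimal()
}

#' Heatmap of referent co-occurrence proportions
#'
#' @param cooc Long table from [cooccurrence()].
#' @return A ggplot object (facetted by system type when present).
#' @export
plot_cooccurrence <- function(cooc) {
  p <- ggplot2::ggplot(cooc,
                       ggplot2::aes(x = .data$referent_i,
                                    y = .data$referent_j,
                                    fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "same term") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if ("system_type" %in% names(cooc))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$system_type))
  p
}
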