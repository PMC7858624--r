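#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   geom_errorbar geom_hline scale_fill_viridis_c labs theme_minimal
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a cohort similarity matrix
#'
#' @param object a `similarity_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = predicted, y = origin, fill = value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(title = paste("Similarity matrix:", attr(object, "kind")),
         x = attr(object, "col_semantics"),
         y = attr(object, "row_semantics"), fill = "value") +
    theme_minimal()
}

#' Per-cohort AUROC of a partition evaluation
#'
#' @param object a `partition_evaluation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.partition_evaluation <- function(object, ...) {
  ggplot(tidy(object), aes(x = cohort, y = mean_auroc)) +
    geom_point() +
    geom_hline(yintercept = object$mean_auroc, linetype = 2) +
    labs(title = sprintf("%s, S = %d: mean AUROC %.3f +/- %.3f",
                         object$kind, object$S, object$mean_auroc,
                         object$ci_halfwidth),
         y = "test AUROC (mean over sub-datasets)") +
    theme_minimal()
}

#' Trade-off plot: detection performance versus training time
#'
#' One point per (matrix kind, S) configuration, with the cohort-specific
#' reference's lower CI bound as the qualification gate.
#'
#' @param sweep_table the `table` of [sweep_supercohorts()] or
#'   [select_partitions()].
#' @param reference optionally, the reference `partition_evaluation` whose
#'   lower CI bound to draw.
#' @return a ggplot.
#' @export
plot_tradeoff <- function(sweep_table, reference = NULL) {
  p <- ggplot(sweep_table,
              aes(x = total_epochs, y = mean_auroc, colour = kind)) +
    geom_point() +
    geom_line(aes(group = kind), alpha = 0.4) +
    labs(x = "total training time (epochs)", y = "mean test AUROC",
         title = "Performance vs number-of-models trade-off") +
    theme_minimal()
  if (!is.null(reference)) {
    p <- p + geom_hline(yintercept = reference$mean_auroc -
                          reference$ci_halfwidth, linetype = 2)
  }
  p
}

#' Plot a cohort dendrogram
#'
#' @param x a `cohort_dendrogram`.
#' @param ... passed to [plot.hclust()].
#' @export
plot.cohort_dendrogram <- function(x, ...) {
  plot(x$hc, main = paste("Ward tree on", x$kind), sub = "", xlab = "", ...)
}
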