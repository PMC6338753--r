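#' Plot library-characterization summaries
#'
#' Four panels: insert-size histogram, genes fully covered per fragment,
#' cumulative gene coverage (% genes with at least k covering fragments),
#' and fragment coverage along the genome in fixed windows.
#'
#' @param object A `dubseq_library_summary` from [summarize_library()].
#' @param ... Unused.
#' @return A patchwork of ggplot panels (or a list of ggplots when
#'   patchwork is unavailable).
#' @export
autoplot.dubseq_library_summary <- function(object, ...) {
  p1 <- ggplot2::ggplot(object$fragment_sizes, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::labs(x = "fragment size (nt)", y = "fragments")
  p2 <- ggplot2::ggplot(object$genes_per_fragment,
                        ggplot2::aes(x = .data$n_genes, y = .data$n_fragments)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "genes fully covered per fragment", y = "fragments")
  p3 <- ggplot2::ggplot(object$cumulative,
                        ggplot2::aes(x = .data$k, y = .data$pct_genes)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "covering fragments (k)", y = "% genes with >= k")
  p4 <- ggplot2::ggplot(object$windows,
                        ggplot2::aes(x = .data$window_start / 1000,
                                     y = .data$n_fragments)) +
    ggplot2::geom_col(width = 9, fill = "grey40") +
    ggplot2::facet_wrap(~contig) +
    ggplot2::labs(x = "genome position (kb)", y = "fragments per window")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    (p1 + p2) / (p3 + p4)
  } else {
    list(p1, p2, p3, p4)
  }
}

#' Plot a fragment-score distribution
#'
#' Histogram of median-centered fragment fitness scores for one experiment.
#'
#' @param fscores Fragment-score tibble from [compute_fragment_scores()].
#' @return A ggplot.
#' @export
plot_fragment_scores <- function(fscores) {
  ggplot2::ggplot(fscores, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "fragment fitness score f", y = "fragments")
}

#' Plot regression versus mean gene scores
#'
#' The regression (NNLS) score against the covering-fragment mean; points
#' off the diagonal toward the mean axis are genes whose mean is inflated by
#' causative neighbors.
#'
#' @param object A `dubseq_gscore` from [fit_gene_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dubseq_gscore <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score_mean, y = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean gene score", y = "regression (NNLS) gene score")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
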