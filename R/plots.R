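#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a PCA sample-QC report
#'
#' PC1/PC2 scatter colored by group; flagged samples are drawn as open
#' triangles.
#'
#' @param object A `sample_qc` report from [pca_sample_qc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_qc <- function(object, ...) {
  ve <- attr(object, "var_explained")
  lab <- function(i) {
    if (!is.null(ve) && is.finite(ve[i])) {
      sprintf("PC%d (%.0f%%)", i, 100 * ve[i])
    } else sprintf("PC%d", i)
  }
  ggplot(object, aes(.data$PC1, .data$PC2, colour = .data$group,
                     shape = .data$flagged)) +
    geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2)) +
    labs(x = lab(1), y = lab(2), shape = "flagged") +
    theme_minimal()
}

#' Plot a mito-stress OCR trace
#'
#' OCR per measurement cycle, colored by injection phase.
#'
#' @param object A [mito_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_trace <- function(object, ...) {
  ggplot(object, aes(.data$cycle, .data$ocr, colour = .data$phase)) +
    geom_line(aes(group = 1), colour = "grey70") +
    geom_point(size = 2.5) +
    labs(x = "measurement cycle", y = "OCR (pmol O2/min)") +
    theme_minimal()
}

#' Plot a per-direction strategy summary
#'
#' Bar chart of sensitive / insensitive gene counts per direction, faceted
#' by strategy.
#'
#' @param summary A `strategy_summary` from [summarize_strategies()].
#' @return A ggplot object.
#' @export
plot_rescue_summary <- function(summary) {
  stopifnot(inherits(summary, "strategy_summary"))
  cells <- dplyr::mutate(summary$cells,
                         status = ifelse(.data$sensitive, "sensitive",
                                         "not sensitive"))
  ggplot(cells, aes(.data$direction, .data$n, fill = .data$status)) +
    geom_col(position = "stack") +
    facet_wrap(~strategy, labeller = ggplot2::as_labeller(
      c(a = "strategy A (DE-based)", b = "strategy B (CI rules)"))) +
    labs(x = "direction in disease", y = "genes", fill = NULL) +
    theme_minimal()
}

#' Plot enrichment results
#'
#' Fold-enrichment versus adjusted p-value for the tested terms, with the
#' significance threshold drawn as a horizontal line.
#'
#' @param object An `enrichment_result` from [hypergeom_enrich()].
#' @param alpha Threshold line (default 1e-6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, alpha = 1e-6, ...) {
  ggplot(object, aes(.data$enrichment_score, -log10(pmax(.data$p_adj, 1e-300)))) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(alpha), linetype = 2) +
    labs(x = "fold enrichment (k/n)/(K/N)", y = "-log10 adjusted p") +
    theme_minimal()
}
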