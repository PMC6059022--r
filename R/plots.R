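#' Volcano display of a differential expression fit
#'
#' @param object An `nb_de` object from [nb_de()].
#' @param fdr_threshold FDR significance threshold for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_de
#' @export
autoplot.nb_de <- function(object, fdr_threshold = 0.05, ...) {
  df <- dplyr::filter(object$results, .data$tested)
  df$significant <- !is.na(df$fdr) & df$fdr < fdr_threshold
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$pvalue, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = paste0("FDR < ", fdr_threshold)
    ) +
    ggplot2::labs(
      x = "log2 fold change (tumor / normal)",
      y = expression(-log[10] ~ "p-value")
    ) +
    ggplot2::theme_minimal()
}

#' Cross-cancer log2 fold-change heatmap
#'
#' Tiles genes by cancers, coloured blue (underexpressed in tumor) to red
#' (overexpressed); cells whose FDR misses the threshold are blank.
#'
#' @param de Differential expression tibble with `gene`, `cancer`, `log2fc`,
#'   `fdr` columns (e.g. the `de` element of an `integrin_study`).
#' @param fdr_threshold Cells at or above this FDR are blanked.
#' @return A ggplot object.
#' @export
plot_log2fc_matrix <- function(de, fdr_threshold = 0.05) {
  if (!"cancer" %in% names(de)) de$cancer <- "study"
  df <- dplyr::mutate(
    de,
    shown = ifelse(!is.na(.data$fdr) & .data$fdr < fdr_threshold,
                   .data$log2fc, NA_real_)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cancer, y = .data$gene, fill = .data$shown
  )) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient2(
      low = "navy", mid = "white", high = "firebrick", midpoint = 0,
      na.value = "white", name = "log2 FC"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Display metric ranks of candidate target genes
#'
#' @param ranked Ranked-target tibble from [rank_targets()] (optionally with a
#'   `cancer` column).
#' @return A ggplot object: genes ordered by metric, shaded light-to-dark
#'   green with increasing rank score; FPKM-failing genes hollow.
#' @export
plot_metric <- function(ranked) {
  if (!"cancer" %in% names(ranked)) ranked$cancer <- "study"
  ggplot2::ggplot(ranked, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$metric), y = .data$metric,
    fill = .data$metric, colour = .data$fpkm_pass
  )) +
    ggplot2::geom_col(linewidth = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~cancer, scales = "free_y") +
    ggplot2::scale_fill_gradient(low = "#d9f0d3", high = "#1b7837",
                                 name = "Metric") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "grey20", `FALSE` = "orange"),
      name = "FPKM pass"
    ) +
    ggplot2::labs(x = NULL, y = "Metric (log2 FC - FDR / 0.05)") +
    ggplot2::theme_minimal()
}

#' Evidence-coloured heterodimer call grid
#'
#' Tiles cancers by heterodimers, coloured by evidence class: RNA-only
#' (blue), IHC-only (red), both (green).
#'
#' @param calls Heterodimer call tibble from [call_heterodimers()] or the
#'   `calls` element of an `integrin_study`.
#' @return A ggplot object.
#' @export
plot_dimer_evidence <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(
    x = .data$cancer, y = .data$display, fill = .data$evidence
  )) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(
      values = c(rna_only = "#2166ac", ihc_only = "#b2182b", both = "#1b7837"),
      name = "Evidence"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_dimer_evidence
#' @param object An `integrin_study` object.
#' @param ... Unused.
#' @method autoplot integrin_study
#' @export
autoplot.integrin_study <- function(object, ...) {
  plot_dimer_evidence(object$calls)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
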