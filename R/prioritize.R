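#' Drug-target ranking metric for overexpressed genes
#'
#' Scores a significantly overexpressed gene as
#' `log2fc - fdr / 0.05`, clamped below at zero. The FDR term divides the
#' adjusted p-value by the 0.05 significance threshold, so an FDR right at the
#' threshold costs one log2 fold-change unit while tiny FDRs cost almost
#' nothing. The metric is only defined for genes that are significantly
#' overexpressed: `fdr < 0.05` (strict) and `log2fc > 0`; everything else
#' returns `NA` and is excluded from ranking. The clamp at zero keeps the
#' reported scale bounded below without discarding near-threshold genes.
#'
#' @param log2fc Numeric vector of log2 fold changes (tumor over normal).
#' @param fdr Numeric vector of BH-adjusted p-values in `[0, 1]`.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return Numeric vector: the non-negative metric, or `NA` where undefined.
#' @examples
#' compute_metric(3, 0.01) # 3 - 0.2 = 2.8
#' compute_metric(2, 0.05) # NA: not strictly below the threshold
#' @export
compute_metric <- function(log2fc, fdr, fdr_threshold = 0.05) {
  if (any(!is.na(fdr) & (fdr < 0 | fdr > 1))) {
    rlang::abort("fdr values must lie in [0, 1].")
  }
  raw <- log2fc - fdr / fdr_threshold
  out <- pmax(raw, 0)
  out[is.na(log2fc) | is.na(fdr) | fdr >= fdr_threshold | log2fc <= 0] <- NA_real_
  out
}

#' Rank overexpressed genes as drug targets and filter on absolute expression
#'
#' Applies [compute_metric()] to a differential expression table, joins
#' per-gene average FPKM values, and flags absolute-expression filters:
#' `fpkm_pass` when the gene's FPKM meets the cutoff (default 10, the
#' conventional moderate-expression threshold) and `fpkm_borderline` when it
#' falls within `borderline_frac` below the cutoff (default 10%), mirroring
#' "just below threshold" genes that remain worth a look. A gene is `eligible`
#' as a pairing subunit when its metric is defined and its FPKM passes.
#'
#' Genes present in the DE table but missing from the FPKM table are kept with
#' missing FPKM, fail the filter, and trigger a warning.
#'
#' @param de Differential expression tibble with columns `gene`, `log2fc`,
#'   `fdr` (e.g. from [nb_wald_test()] or `tidy()` of [nb_de()]).
#' @param fpkm Tibble with columns `gene` and `fpkm` (average FPKM per gene).
#' @param cutoff Positive FPKM cutoff, default 10.
#' @param borderline_frac Width of the borderline band as a fraction below the
#'   cutoff, default 0.10.
#' @param fdr_threshold Significance threshold passed to [compute_metric()].
#' @return A tibble with columns `gene`, `metric`, `log2fc`, `fdr`, `fpkm`,
#'   `fpkm_pass`, `fpkm_borderline`, `eligible`, sorted by metric descending
#'   (ties broken by gene symbol), one row per gene with a defined metric.
#' @examples
#' de <- tibble::tibble(gene = c("ITGA6", "ITGB4"), log2fc = c(2, 3),
#'                      fdr = c(0.001, 0.01))
#' fpkm <- tibble::tibble(gene = c("ITGA6", "ITGB4"), fpkm = c(50, 9.5))
#' rank_targets(de, fpkm)
#' @export
rank_targets <- function(de, fpkm, cutoff = 10, borderline_frac = 0.10,
                         fdr_threshold = 0.05) {
  stopifnot(cutoff > 0, borderline_frac >= 0)
  ranked <- de |>
    dplyr::mutate(metric = compute_metric(.data$log2fc, .data$fdr, fdr_threshold)) |>
    dplyr::filter(!is.na(.data$metric))
  missing <- setdiff(ranked$gene, fpkm$gene)
  if (length(missing) > 0) {
    rlang::warn(paste0(
      "No FPKM value for gene(s): ", paste(missing, collapse = ", "),
      "; treated as failing the expression filter."
    ))
  }
  ranked |>
    dplyr::left_join(fpkm[c("gene", "fpkm")], by = "gene") |>
    dplyr::mutate(
      fpkm_pass = !is.na(.data$fpkm) & .data$fpkm >= cutoff,
      fpkm_borderline = !is.na(.data$fpkm) &
        .data$fpkm >= (1 - borderline_frac) * cutoff & .data$fpkm < cutoff,
      eligible = .data$fpkm_pass
    ) |>
    dplyr::arrange(dplyr::desc(.data$metric), .data$gene) |>
    dplyr::select("gene", "metric", "log2fc", "fdr", "fpkm",
                  "fpkm_pass", "fpkm_borderline", "eligible")
}

#' Average FPKM from counts and gene lengths
#'
#' Convenience conversion when no external FPKM table is available:
#' FPKM = count / (transcript length in kb x mapped fragments in millions),
#' averaged over the selected samples (tumor samples by default, matching the
#' use of FPKM as a tumor absolute-expression filter).
#'
#' @param counts Raw count tibble (gene column + sample columns).
#' @param gene_lengths Tibble with columns `gene` and `length` (transcript
#'   length in bases).
#' @param meta Optional metadata tibble; when given with
#'   `samples = "tumor"`, only tumor samples enter the average.
#' @param samples `"tumor"`, `"normal"` or `"all"`.
#' @param gene_col Name of the gene column.
#' @return A tibble with columns `gene` and `fpkm`.
#' @export
compute_fpkm <- function(counts, gene_lengths, meta = NULL, samples = "tumor",
                         gene_col = "gene") {
  m <- as_count_matrix(counts, gene_col)
  if (!is.null(meta) && samples != "all") {
    keep <- meta$sample_id[meta$condition == samples]
    keep <- intersect(colnames(m), keep)
    if (length(keep) == 0) {
      rlang::abort(paste0("No '", samples, "' samples found for the FPKM average."))
    }
    m <- m[, keep, drop = FALSE]
  }
  len <- setNames(gene_lengths$length, gene_lengths$gene)[rownames(m)]
  if (anyNA(len) || any(len <= 0)) {
    rlang::abort("Every counted gene needs a positive length in gene_lengths.")
  }
  libsize <- colSums(m)
  fpkm_mat <- sweep(m / (len / 1e3), 2, libsize / 1e6, `/`)
  tibble::tibble(gene = rownames(m), fpkm = unname(rowMeans(fpkm_mat)))
}
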