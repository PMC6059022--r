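#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential expression fit
#'
#' @param x An `nb_de` object from [nb_de()].
#' @param ... Unused.
#' @return The per-gene result tibble: `gene`, `log2fc`, `pvalue`, `fdr`,
#'   `mean_normalized_count`, `tested`.
#' @method tidy nb_de
#' @export
tidy.nb_de <- function(x, ...) {
  x$results
}

#' One-row summary of a differential expression fit
#'
#' @param x An `nb_de` object.
#' @param ... Unused.
#' @return A one-row tibble: gene counts, sample counts, and the number of
#'   genes with `fdr < 0.05`.
#' @method glance nb_de
#' @export
glance.nb_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_tested = sum(x$results$tested),
    n_significant = sum(x$results$fdr < 0.05, na.rm = TRUE),
    n_tumor = x$n_tumor,
    n_normal = x$n_normal,
    median_dispersion = stats::median(x$dispersion$dispersion, na.rm = TRUE)
  )
}

#' Tidy a pipeline result
#'
#' @param x An `integrin_study` object from [run_pipeline()].
#' @param ... Unused.
#' @return The heterodimer call tibble (cancer, pair, mode, evidence).
#' @method tidy integrin_study
#' @export
tidy.integrin_study <- function(x, ...) {
  x$calls
}

#' One-row summary of a pipeline result
#'
#' @param x An `integrin_study` object.
#' @param ... Unused.
#' @return A one-row tibble with study-level counts.
#' @method glance integrin_study
#' @export
glance.integrin_study <- function(x, ...) {
  tibble::tibble(
    n_cancers = x$summary$n_cancers,
    mode = x$summary$mode,
    n_genes_tested = sum(x$de$tested),
    n_eligible_subunits = sum(x$ranked$eligible),
    n_heterodimer_calls = nrow(x$calls),
    n_both_evidence = sum(x$calls$evidence == "both")
  )
}
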