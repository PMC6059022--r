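#' Read pipeline input tables
#'
#' Thin TSV readers for the pipeline's input dialects: a raw count table
#' (gene column + integer sample columns), sample metadata
#' (`sample_id`, `condition`), an average-FPKM table (`gene`, `fpkm`) and an
#' IHC tally table (`gene`, `cancer`, four level tallies, `normal_level`).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname readers
#' @export
read_meta <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' @rdname readers
#' @export
read_fpkm <- function(path) {
  readr::read_tsv(path, col_types = "cd")
}

#' @rdname readers
#' @export
read_ihc_tally <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a study configuration from YAML
#'
#' The YAML lists per-cancer input paths and the study thresholds, e.g.:
#' \preformatted{
#' cancers:
#'   PAAD:
#'     counts: paad/counts.tsv
#'     meta: paad/meta.tsv
#'     fpkm: paad/fpkm.tsv
#'     ihc: paad/ihc.tsv     # optional
#' thresholds:
#'   fdr: 0.05
#'   fpkm_cutoff: 10
#'   borderline_frac: 0.10
#' mode: strict
#' output_dir: results/
#' }
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A study configuration list for [run_pipeline()].
#' @export
read_study_config <- function(path) {
  config <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  config$cancers <- lapply(config$cancers, function(cz) {
    lapply(cz, function(p) {
      if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
        file.path(base, p)
      } else {
        p
      }
    })
  })
  config
}

resolve_input <- function(x, reader, what, cancer) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  if (is.character(x)) {
    if (!file.exists(x)) {
      rlang::abort(paste0("Input '", what, "' for cancer ", cancer,
                          " not found: ", x))
    }
    return(reader(x))
  }
  rlang::abort(paste0("Input '", what, "' for cancer ", cancer,
                      " must be a path or a data frame."))
}

#' Run the full target-selection pipeline over one or more cancers
#'
#' Executes, per cancer: differential expression ([nb_de()]), metric ranking
#' and FPKM filtering ([rank_targets()]), IHC scoring ([score_ihc()], when an
#' IHC table is supplied) and heterodimer calling with evidence integration
#' ([call_heterodimers()]). Cross-cancer summary artifacts are assembled: the
#' genes-by-cancers log2 fold-change matrix (cells blanked where the FDR
#' misses the threshold, [export_matrix()]) and the heterodimer evidence
#' table. The run is deterministic for fixed inputs.
#'
#' @param config A list (or [read_study_config()] result) with elements:
#'   `cancers` — named list, each with `counts`, `meta`, optional `fpkm`,
#'   `gene_lengths`, `ihc` (paths or data frames); `thresholds` — optional
#'   list with `fdr` (0.05), `fpkm_cutoff` (10), `borderline_frac` (0.10);
#'   `mode` — `"strict"` (default) or `"relaxed"`; optional `ihc_map` with
#'   columns `ihc_cancer`, `cancer`; optional `output_dir`.
#' @return An object of class `integrin_study`: a list of tibbles `de`,
#'   `ranked`, `ihc_scores`, `calls`, `matrix_log2fc` and a `summary` list.
#'   With `output_dir` set, also writes `de/<cancer>.tsv`,
#'   `ranked/<cancer>.tsv`, `ihc_scores.tsv`, `calls.tsv`,
#'   `matrix_log2fc.tsv` and `summary.json`.
#' @examples
#' demo <- make_demo_study(seed = 1)
#' res <- run_pipeline(list(cancers = list(DEMO = demo)))
#' res$calls
#' @export
run_pipeline <- function(config) {
  if (is.null(config$cancers) || length(config$cancers) == 0) {
    rlang::abort("Study configuration lists no cancers.")
  }
  thr <- config$thresholds
  fdr_thr <- thr$fdr %||% 0.05
  fpkm_cutoff <- thr$fpkm_cutoff %||% 10
  borderline_frac <- thr$borderline_frac %||% 0.10
  mode <- config$mode %||% "strict"
  catalog <- load_catalog()
  rules <- config$rules %||% load_pairing_rules(catalog = catalog)
  if (is.character(rules)) rules <- load_pairing_rules(rules, catalog)

  de_all <- list()
  ranked_all <- list()
  ihc_all <- list()
  for (cz in names(config$cancers)) {
    inp <- config$cancers[[cz]]
    counts <- resolve_input(inp$counts, read_counts, "counts", cz)
    meta <- resolve_input(inp$meta, read_meta, "meta", cz)
    if (is.null(counts) || is.null(meta)) {
      rlang::abort(paste0("Cancer ", cz, " needs both 'counts' and 'meta' inputs."))
    }
    gene_factors <- resolve_input(inp$gene_factors, read_counts, "gene_factors", cz)
    fit <- nb_de(counts, meta, gene_factors = gene_factors)
    de <- tidy(fit)
    fpkm <- resolve_input(inp$fpkm, read_fpkm, "fpkm", cz)
    if (is.null(fpkm)) {
      lengths <- resolve_input(inp$gene_lengths, read_counts, "gene_lengths", cz)
      if (is.null(lengths)) {
        rlang::abort(paste0("Cancer ", cz, " needs either 'fpkm' or 'gene_lengths'."))
      }
      fpkm <- compute_fpkm(counts, lengths, meta)
    }
    ranked <- rank_targets(de, fpkm,
      cutoff = fpkm_cutoff,
      borderline_frac = borderline_frac, fdr_threshold = fdr_thr
    )
    de_all[[cz]] <- dplyr::mutate(de, cancer = cz, .before = 1)
    ranked_all[[cz]] <- dplyr::mutate(ranked, cancer = cz, .before = 1)
    ihc_in <- resolve_input(inp$ihc, read_ihc_tally, "ihc", cz)
    if (!is.null(ihc_in)) {
      sc <- score_ihc(ihc_in)
      sc$cancer <- cz
      ihc_all[[cz]] <- sc
    }
  }
  de <- dplyr::bind_rows(de_all)
  ranked <- dplyr::bind_rows(ranked_all)
  ihc_scores <- if (length(ihc_all) > 0) dplyr::bind_rows(ihc_all) else NULL
  if (!is.null(ihc_scores) && !is.null(config$ihc_map)) {
    map <- tibble::as_tibble(config$ihc_map)
    mapped <- ihc_scores |>
      dplyr::inner_join(map, by = c(cancer = "ihc_cancer"),
                        suffix = c("", ".subtype")) |>
      dplyr::mutate(cancer = .data$cancer.subtype) |>
      dplyr::select(-"cancer.subtype")
    ihc_scores <- dplyr::bind_rows(
      dplyr::filter(ihc_scores, !.data$cancer %in% map$ihc_cancer), mapped
    )
  }
  calls <- call_heterodimers(
    ranked, ihc_scores,
    mode = mode, rules = rules, catalog = catalog,
    fpkm_cutoff = fpkm_cutoff
  )
  mat <- export_matrix(de, fdr_threshold = fdr_thr)
  result <- structure(
    list(
      de = de, ranked = ranked, ihc_scores = ihc_scores, calls = calls,
      matrix_log2fc = mat,
      summary = list(
        n_cancers = length(config$cancers),
        thresholds = list(fdr = fdr_thr, fpkm_cutoff = fpkm_cutoff,
                          borderline_frac = borderline_frac),
        mode = mode,
        per_cancer = lapply(stats::setNames(nm = names(config$cancers)), function(cz) {
          list(
            n_tested = sum(de$tested[de$cancer == cz]),
            n_significant = sum(de$fdr[de$cancer == cz] < fdr_thr, na.rm = TRUE),
            n_eligible = sum(ranked$eligible[ranked$cancer == cz]),
            heterodimers = calls$name[calls$cancer == cz]
          )
        })
      )
    ),
    class = "integrin_study"
  )
  if (!is.null(config$output_dir)) {
    write_study_outputs(result, config$output_dir)
  }
  result
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_study_outputs <- function(result, output_dir) {
  dir.create(file.path(output_dir, "de"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "ranked"), recursive = TRUE, showWarnings = FALSE)
  for (cz in unique(result$de$cancer)) {
    readr::write_tsv(
      dplyr::filter(result$de, .data$cancer == cz),
      file.path(output_dir, "de", paste0(cz, ".tsv"))
    )
    readr::write_tsv(
      dplyr::filter(result$ranked, .data$cancer == cz),
      file.path(output_dir, "ranked", paste0(cz, ".tsv"))
    )
  }
  if (!is.null(result$ihc_scores)) {
    readr::write_tsv(result$ihc_scores, file.path(output_dir, "ihc_scores.tsv"))
  }
  readr::write_tsv(result$calls, file.path(output_dir, "calls.tsv"))
  readr::write_tsv(result$matrix_log2fc, file.path(output_dir, "matrix_log2fc.tsv"))
  jsonlite::write_json(result$summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

#' Genes-by-cancers log2 fold-change matrix
#'
#' Spreads per-cancer differential expression results into a wide genes-by-
#' cancers table of log2 fold changes, blanking (NA) every cell whose FDR is
#' not below the threshold — the "void value" convention of cross-cancer
#' expression heatmaps. Optionally adds linear fold-change columns with the
#' signed-reciprocal display convention: `2^log2fc` when `log2fc >= 0`, else
#' `-2^(-log2fc)` (so a halving shows as -2, a display convention only).
#'
#' @param de Differential expression tibble with columns `gene`, `log2fc`,
#'   `fdr` and (for several cancers) `cancer`.
#' @param fdr_threshold Significance threshold below which a cell is shown.
#' @param linear If `TRUE`, report signed linear fold changes instead of
#'   log2 values.
#' @return A wide tibble, one row per gene, one column per cancer.
#' @export
export_matrix <- function(de, fdr_threshold = 0.05, linear = FALSE) {
  if (!"cancer" %in% names(de)) de$cancer <- "study"
  cell <- ifelse(!is.na(de$fdr) & de$fdr < fdr_threshold, de$log2fc, NA_real_)
  if (linear) {
    cell <- ifelse(cell >= 0, 2^cell, -2^(-cell))
  }
  de |>
    dplyr::mutate(.cell = cell) |>
    dplyr::select("gene", "cancer", ".cell") |>
    tidyr::pivot_wider(names_from = "cancer", values_from = ".cell") |>
    dplyr::arrange(.data$gene)
}

#' @export
print.integrin_study <- function(x, ...) {
  cat("Integrin target-selection study\n")
  cat("  cancers:", paste(unique(x$de$cancer), collapse = ", "), "\n")
  cat("  mode:", x$summary$mode, "\n")
  cat("  heterodimer calls:", nrow(x$calls), "\n")
  invisible(x)
}
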