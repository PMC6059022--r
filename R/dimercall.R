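check_pass_set <- function(pass_genes, catalog) {
  pass_genes <- unique(as.character(pass_genes))
  unknown <- setdiff(pass_genes, catalog$gene)
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "Pass set contains gene(s) absent from the subunit catalog: ",
      paste(unknown, collapse = ", ")
    ))
  }
  pass_genes
}

#' Strict heterodimer calls: both subunits must pass
#'
#' Returns every allowed (alpha, beta) heterodimer whose two subunit genes are
#' both in the pass set — the conservative receptor-level call, appropriate
#' when a drug target should be overexpressed as a whole receptor.
#'
#' @param pass_genes Character vector of subunit genes that passed the
#'   subunit-level filters (e.g. `eligible` genes from [rank_targets()], or
#'   IHC-overexpressed genes from [score_ihc()]).
#' @param rules Pairing rules from [load_pairing_rules()].
#' @param catalog Subunit catalog from [load_catalog()].
#' @return A tibble of calls: `alpha_gene`, `beta_gene`, `name`, `display`,
#'   `mode = "strict"`, `n_pass_subunits = 2`; ordered by beta then alpha gene.
#' @examples
#' call_strict(c("ITGA6", "ITGB4")) # the a6b4 receptor
#' @export
call_strict <- function(pass_genes, rules = load_pairing_rules(),
                        catalog = load_catalog()) {
  pass_genes <- check_pass_set(pass_genes, catalog)
  enumerate_heterodimers(catalog, rules) |>
    dplyr::filter(.data$alpha_gene %in% pass_genes,
                  .data$beta_gene %in% pass_genes) |>
    dplyr::mutate(mode = "strict", n_pass_subunits = 2L)
}

#' Relaxed heterodimer calls: one passing subunit suffices
#'
#' Returns every allowed heterodimer with at least one subunit in the pass
#' set. The rationale: a highly expressed subunit can drive surface expression
#' of the whole receptor even when its obligate partner sits at normal
#' levels, so single-subunit overexpression can still mark a viable target.
#' `n_pass_subunits` records whether one or both subunits passed (2 implies
#' the pair is also a strict call).
#'
#' @inheritParams call_strict
#' @param partner_ok Optional character vector restricting the *silent*
#'   partner: a single-subunit call is only emitted when its non-passing
#'   partner is in `partner_ok` (e.g. genes with adequate absolute
#'   expression). `NULL` (default) places no requirement on the partner.
#' @return A tibble of calls as in [call_strict()] with `mode = "relaxed"` and
#'   `n_pass_subunits` in `{1, 2}`.
#' @examples
#' call_relaxed("ITGAV") # the five alpha-v receptors
#' @export
call_relaxed <- function(pass_genes, rules = load_pairing_rules(),
                         catalog = load_catalog(), partner_ok = NULL) {
  pass_genes <- check_pass_set(pass_genes, catalog)
  if (!is.null(partner_ok)) partner_ok <- check_pass_set(partner_ok, catalog)
  out <- enumerate_heterodimers(catalog, rules) |>
    dplyr::mutate(
      n_pass_subunits = (.data$alpha_gene %in% pass_genes) +
        (.data$beta_gene %in% pass_genes)
    ) |>
    dplyr::filter(.data$n_pass_subunits >= 1L)
  if (!is.null(partner_ok)) {
    out <- out |>
      dplyr::filter(
        .data$n_pass_subunits == 2L |
          (.data$alpha_gene %in% pass_genes & .data$beta_gene %in% partner_ok) |
          (.data$beta_gene %in% pass_genes & .data$alpha_gene %in% partner_ok)
      )
  }
  dplyr::mutate(out, mode = "relaxed",
                n_pass_subunits = as.integer(.data$n_pass_subunits)) |>
    dplyr::select("alpha_gene", "beta_gene", "name", "display",
                  "mode", "n_pass_subunits")
}

#' Classify heterodimer calls by supporting evidence
#'
#' Partitions the union of RNA-derived and IHC-derived heterodimer calls into
#' three evidence classes: supported by the transcriptome analysis only
#' (`rna_only`), by immunohistochemistry only (`ihc_only`), or by both
#' (`both`). Heterodimers called by neither modality are absent from the
#' result.
#'
#' @param rna_calls,ihc_calls Heterodimer call tibbles (from [call_strict()] /
#'   [call_relaxed()]) or character vectors of heterodimer `name`s.
#' @return A tibble with columns `name` and `evidence`, sorted by `name`.
#' @examples
#' integrate_evidence(c("ITGA6/ITGB4", "ITGAV/ITGB6"), "ITGAV/ITGB6")
#' @export
integrate_evidence <- function(rna_calls, ihc_calls) {
  as_names <- function(x) {
    if (is.data.frame(x)) unique(x$name) else unique(as.character(x))
  }
  rna <- as_names(rna_calls)
  ihc <- as_names(ihc_calls)
  all_calls <- sort(union(rna, ihc))
  tibble::tibble(
    name = all_calls,
    evidence = dplyr::case_when(
      all_calls %in% rna & all_calls %in% ihc ~ "both",
      all_calls %in% rna ~ "rna_only",
      TRUE ~ "ihc_only"
    )
  )
}

#' Per-cancer heterodimer target calls with evidence integration
#'
#' Combines subunit-level RNA results ([rank_targets()]) and optional IHC
#' scores ([score_ihc()]) into receptor-level target calls per cancer.
#' RNA pass sets are the `eligible` genes (defined metric and FPKM pass); IHC
#' pass sets are the `overexpressed` genes. Each modality's pass set is paired
#' under the rules (RNA in the requested `mode`; IHC strict by default, the
#' convention for protein-level validation) and the resulting calls are
#' labelled with their evidence class.
#'
#' IHC atlases report by organ rather than cancer subtype; supply `ihc_map`
#' (columns `ihc_cancer`, `cancer`) to apply one organ-level IHC record to
#' several subtypes (e.g. lung IHC to both lung adeno- and squamous
#' carcinoma).
#'
#' @param ranked Ranked-target tibble from [rank_targets()], optionally with a
#'   `cancer` column for multi-cancer input.
#' @param ihc_scores Optional scored IHC tibble from [score_ihc()].
#' @param mode `"strict"` (both subunits must be eligible) or `"relaxed"`
#'   (one eligible subunit suffices) for the RNA side.
#' @param ihc_mode Pairing mode for the IHC side, default `"strict"`.
#' @param rules,catalog Pairing rules and subunit catalog.
#' @param allow_borderline_anchor If `TRUE`, genes in the borderline FPKM band
#'   also anchor RNA calls; default `FALSE` (borderline genes do not anchor).
#' @param relaxed_partner_fpkm If `TRUE`, a relaxed single-subunit RNA call
#'   additionally requires the silent partner to pass the FPKM cutoff
#'   (partner FPKMs taken from `fpkm`).
#' @param fpkm Optional full FPKM tibble (`gene`, `fpkm`), needed only for
#'   `relaxed_partner_fpkm = TRUE`.
#' @param fpkm_cutoff FPKM cutoff used for the partner requirement.
#' @return A tibble with columns `cancer`, `name`, `alpha_gene`, `beta_gene`,
#'   `display`, `mode`, `n_pass_subunits`, `evidence`.
#' @export
call_heterodimers <- function(ranked, ihc_scores = NULL,
                              mode = c("strict", "relaxed"),
                              ihc_mode = "strict",
                              rules = load_pairing_rules(),
                              catalog = load_catalog(),
                              allow_borderline_anchor = FALSE,
                              relaxed_partner_fpkm = FALSE,
                              fpkm = NULL, fpkm_cutoff = 10) {
  mode <- match.arg(mode)
  if (!"cancer" %in% names(ranked)) ranked$cancer <- "study"
  if (!is.null(ihc_scores) && !"cancer" %in% names(ihc_scores)) {
    ihc_scores$cancer <- "study"
  }
  partner_ok <- NULL
  if (relaxed_partner_fpkm) {
    if (is.null(fpkm)) {
      rlang::abort("relaxed_partner_fpkm = TRUE requires an fpkm table.")
    }
    partner_ok <- fpkm$gene[!is.na(fpkm$fpkm) & fpkm$fpkm >= fpkm_cutoff]
    partner_ok <- intersect(partner_ok, catalog$gene)
  }

  rna_call_fun <- function(pass) {
    if (mode == "strict") {
      call_strict(pass, rules, catalog)
    } else {
      call_relaxed(pass, rules, catalog, partner_ok = partner_ok)
    }
  }
  ihc_call_fun <- function(pass) {
    if (ihc_mode == "strict") {
      call_strict(pass, rules, catalog)
    } else {
      call_relaxed(pass, rules, catalog)
    }
  }

  dimers <- enumerate_heterodimers(catalog, rules)
  empty_calls <- tibble::tibble(
    cancer = character(), name = character(), alpha_gene = character(),
    beta_gene = character(), display = character(), mode = character(),
    n_pass_subunits = integer(), evidence = character()
  )
  out <- purrr::map(sort(unique(ranked$cancer)), function(cz) {
    rk <- dplyr::filter(ranked, .data$cancer == cz)
    pass <- rk$gene[rk$eligible]
    if (allow_borderline_anchor) {
      pass <- union(pass, rk$gene[rk$fpkm_borderline])
    }
    rna <- rna_call_fun(pass)
    ihc <- NULL
    if (!is.null(ihc_scores)) {
      sc <- dplyr::filter(ihc_scores, .data$cancer == cz)
      if (nrow(sc) > 0) {
        ihc <- ihc_call_fun(sc$gene[sc$overexpressed])
      }
    }
    ev <- integrate_evidence(rna, if (is.null(ihc)) character(0) else ihc)
    if (nrow(ev) == 0) return(NULL)
    npass <- setNames(rna$n_pass_subunits, rna$name)
    if (!is.null(ihc)) {
      ihc_np <- setNames(ihc$n_pass_subunits, ihc$name)
      only_ihc <- setdiff(names(ihc_np), names(npass))
      npass <- c(npass, ihc_np[only_ihc])
    }
    ev |>
      dplyr::left_join(dimers, by = "name") |>
      dplyr::mutate(
        cancer = cz,
        mode = ifelse(.data$evidence == "ihc_only", ihc_mode, mode),
        n_pass_subunits = as.integer(npass[.data$name])
      ) |>
      dplyr::select("cancer", "name", "alpha_gene", "beta_gene", "display",
                    "mode", "n_pass_subunits", "evidence")
  }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) empty_calls else out
}
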