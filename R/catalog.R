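#' The integrin subunit catalog
#'
#' Loads the catalog of the 27 integrin subunit genes: 18 alpha chains and
#' 9 beta chains. Integrins are heterodimeric cell-surface receptors built
#' from one alpha and one beta subunit; the catalog names each subunit by its
#' HGNC gene symbol together with its chain class and the conventional protein
#' display name (e.g. `ITGAV` is the \eqn{\alpha}v chain).
#'
#' The packaged default encodes the canonical human repertoire. The gene-level
#' identity of the 18th alpha chain is `ITGA2B` (\eqn{\alpha}IIb, the platelet
#' fibrinogen-receptor chain), which the literature's 24-heterodimer table
#' requires even though alpha-subunit lists are often written out only for the
#' first 17.
#'
#' @param path Path to a catalog JSON file with a `genes` array of
#'   `{gene, chain, display}` records. `NULL` (default) loads the packaged
#'   catalog.
#'
#' @return A tibble with columns `gene` (HGNC symbol), `chain`
#'   (`"alpha"`/`"beta"`) and `display`, one row per subunit.
#' @examples
#' cat27 <- load_catalog()
#' dplyr::count(cat27, chain)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "integrin_catalog.json", package = "dimertarget")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) {
      rlang::abort(paste0("Cannot parse catalog resource '", path, "': ", conditionMessage(e)))
    }
  )
  if (is.null(raw$genes)) {
    rlang::abort("Catalog resource has no 'genes' field.")
  }
  catalog <- tibble::as_tibble(raw$genes)
  validate_catalog(catalog)
}

validate_catalog <- function(catalog) {
  required <- c("gene", "chain", "display")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    rlang::abort(paste0("Catalog is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_chain <- dplyr::filter(catalog, !.data$chain %in% c("alpha", "beta"))
  if (nrow(bad_chain) > 0) {
    rlang::abort(paste0(
      "Catalog row for gene '", bad_chain$gene[[1]],
      "' has chain '", bad_chain$chain[[1]], "'; must be 'alpha' or 'beta'."
    ))
  }
  dup <- catalog$gene[duplicated(catalog$gene)]
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicate gene symbol(s) in catalog: ", paste(unique(dup), collapse = ", ")))
  }
  n_alpha <- sum(catalog$chain == "alpha")
  n_beta <- sum(catalog$chain == "beta")
  if (nrow(catalog) != 27 || n_alpha != 18 || n_beta != 9) {
    rlang::abort(paste0(
      "Catalog must contain 27 subunit genes (18 alpha, 9 beta); got ",
      nrow(catalog), " (", n_alpha, " alpha, ", n_beta, " beta)."
    ))
  }
  catalog[c("gene", "chain", "display")]
}

#' Integrin alpha/beta pairing rules
#'
#' Loads the table of allowed (alpha, beta) subunit combinations — the fixed
#' combinatorics by which the 27 subunit genes assemble into the 24 known
#' functional heterodimeric receptors. `ITGBL1` (beta-like 1) has no known
#' alpha partner and appears in no pair; `ITGB4` pairs exclusively with
#' `ITGA6`; `ITGAV` is the most promiscuous chain, pairing with five beta
#' subunits.
#'
#' @param path Path to a JSON file with a `pairs` array of
#'   `[alpha_gene, beta_gene]` two-element arrays; `NULL` loads the packaged
#'   rules.
#' @param catalog Subunit catalog tibble used for validation, from
#'   [load_catalog()].
#'
#' @return A tibble with columns `alpha_gene`, `beta_gene`, `name`
#'   (`"ITGAx/ITGBy"`) and `display` (e.g. `"αvβ3"`), one row per allowed
#'   heterodimer.
#' @examples
#' rules <- load_pairing_rules()
#' nrow(rules) # 24
#' @export
load_pairing_rules <- function(path = NULL, catalog = load_catalog()) {
  if (is.null(path)) {
    path <- system.file("extdata", "integrin_catalog.json", package = "dimertarget")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyMatrix = TRUE),
    error = function(e) {
      rlang::abort(paste0("Cannot parse pairing-rule resource '", path, "': ", conditionMessage(e)))
    }
  )
  if (is.null(raw$pairs)) {
    rlang::abort("Pairing-rule resource has no 'pairs' field.")
  }
  pairs <- raw$pairs
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  rules <- tibble::tibble(alpha_gene = pairs[, 1], beta_gene = pairs[, 2])
  validate_pairing_rules(rules, catalog)
}

validate_pairing_rules <- function(rules, catalog) {
  alpha_ok <- catalog$gene[catalog$chain == "alpha"]
  beta_ok <- catalog$gene[catalog$chain == "beta"]
  unknown <- setdiff(c(rules$alpha_gene, rules$beta_gene), catalog$gene)
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "Pairing rule references gene(s) absent from the catalog: ",
      paste(unknown, collapse = ", ")
    ))
  }
  wrong_alpha <- setdiff(rules$alpha_gene, alpha_ok)
  wrong_beta <- setdiff(rules$beta_gene, beta_ok)
  if (length(wrong_alpha) > 0 || length(wrong_beta) > 0) {
    rlang::abort(paste0(
      "Pairing rule places gene(s) on the wrong chain: ",
      paste(c(wrong_alpha, wrong_beta), collapse = ", ")
    ))
  }
  if (anyDuplicated(paste(rules$alpha_gene, rules$beta_gene))) {
    rlang::abort("Duplicate (alpha, beta) pair in the pairing rules.")
  }
  disp <- stats::setNames(catalog$display, catalog$gene)
  dplyr::mutate(
    rules,
    name = paste0(.data$alpha_gene, "/", .data$beta_gene),
    display = paste0(disp[.data$alpha_gene], disp[.data$beta_gene])
  )
}

#' Enumerate the legal integrin heterodimers
#'
#' Lists every allowed (alpha, beta) heterodimer exactly once, in a stable
#' deterministic order (beta gene, then alpha gene). With the packaged catalog
#' and rules this yields the 24 functional integrin receptors.
#'
#' @param catalog Subunit catalog tibble from [load_catalog()].
#' @param rules Pairing-rule tibble from [load_pairing_rules()].
#'
#' @return A tibble with columns `alpha_gene`, `beta_gene`, `name`, `display`,
#'   sorted by `beta_gene` then `alpha_gene`.
#' @examples
#' enumerate_heterodimers()
#' @export
enumerate_heterodimers <- function(catalog = load_catalog(),
                                   rules = load_pairing_rules(catalog = catalog)) {
  rules <- validate_pairing_rules(rules[c("alpha_gene", "beta_gene")], catalog)
  dplyr::arrange(rules, .data$beta_gene, .data$alpha_gene)
}

#' Obligate pairing partners of a subunit gene
#'
#' @param gene A single HGNC subunit gene symbol.
#' @param rules Pairing-rule tibble from [load_pairing_rules()].
#' @param catalog Subunit catalog tibble used to check the gene exists.
#'
#' @return A character vector of partner gene symbols (possibly empty:
#'   `ITGBL1` has no identified partner).
#' @examples
#' partners_of("ITGB4") # "ITGA6"
#' partners_of("ITGBL1") # character(0)
#' @export
partners_of <- function(gene, rules = load_pairing_rules(), catalog = load_catalog()) {
  stopifnot(is.character(gene), length(gene) == 1)
  if (!gene %in% catalog$gene) {
    rlang::abort(paste0("Unknown subunit gene '", gene, "'."))
  }
  sort(unique(c(
    rules$alpha_gene[rules$beta_gene == gene],
    rules$beta_gene[rules$alpha_gene == gene]
  )))
}
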