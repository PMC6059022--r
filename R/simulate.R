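#' Configuration for a synthetic tumor/normal cohort
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' generator emulates the statistical structure the pipeline assumes: raw
#' counts that are negative-binomially distributed (variance
#' \eqn{\mu + \alpha\mu^2}) with gene-specific dispersions, planted
#' tumor-vs-normal fold changes, per-sample library-size factors, optional
#' log-normal gene-by-sample factor structure, a per-gene average FPKM table,
#' and multinomial IHC staining tallies with a planted overexpression pattern.
#'
#' @param genes Character vector of gene symbols (default: the 27 integrin
#'   subunits) or a catalog tibble from [load_catalog()].
#' @param n_tumor,n_normal Samples per condition (default 50 each).
#' @param baseline_mean NB mean in normal samples; scalar or per-gene vector
#'   (default 100).
#' @param dispersion NB dispersion alpha; scalar or per-gene (default 0.1).
#' @param planted_log2fc True tumor/normal log2 fold change; scalar, or a
#'   named vector giving values for a subset of genes (others 0).
#' @param library_size_sd Standard deviation (log scale) of the log-normal
#'   per-sample library-size factors (default 0.15).
#' @param gene_factor_sd Log-scale spread of gene-by-sample technical factors
#'   (default 0: none).
#' @param fpkm_map Named per-gene average FPKM values; scalar recycled.
#' @param ihc_pattern Named list per gene: `list(probs = c(not_detected, low,
#'   medium, high), normal = <level>)`. Genes may instead map to `NULL`,
#'   meaning no IHC data. Default: every gene stains exactly at a `"medium"`
#'   normal level (no planted protein overexpression).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genes = load_catalog(),
                       n_tumor = 50, n_normal = 50,
                       baseline_mean = 100, dispersion = 0.1,
                       planted_log2fc = 0,
                       library_size_sd = 0.15, gene_factor_sd = 0,
                       fpkm_map = 20,
                       ihc_pattern = NULL,
                       seed = 1L) {
  if (is.data.frame(genes)) genes <- genes$gene
  stopifnot(length(genes) >= 1, !anyDuplicated(genes))
  if (n_tumor < 1 || n_normal < 1) rlang::abort("Need at least one sample per condition.")
  expand <- function(x, what, allow_zero = FALSE) {
    if (!is.null(names(x))) {
      full <- setNames(rep(0, length(genes)), genes)
      unknown <- setdiff(names(x), genes)
      if (length(unknown) > 0) {
        rlang::abort(paste0("Unknown gene(s) in ", what, ": ", paste(unknown, collapse = ", ")))
      }
      full[names(x)] <- x
      full
    } else if (length(x) == 1) {
      setNames(rep(x, length(genes)), genes)
    } else if (length(x) == length(genes)) {
      setNames(x, genes)
    } else {
      rlang::abort(paste0(what, " must be scalar, named, or per-gene."))
    }
  }
  baseline_mean <- expand(baseline_mean, "baseline_mean")
  dispersion <- expand(dispersion, "dispersion")
  planted_log2fc <- expand(planted_log2fc, "planted_log2fc")
  fpkm_map <- expand(fpkm_map, "fpkm_map")
  if (any(baseline_mean <= 0)) rlang::abort("baseline_mean must be positive.")
  if (any(dispersion < 0)) rlang::abort("dispersion must be non-negative.")
  if (any(fpkm_map < 0)) rlang::abort("fpkm_map must be non-negative.")
  if (library_size_sd < 0 || gene_factor_sd < 0) {
    rlang::abort("library_size_sd and gene_factor_sd must be non-negative.")
  }
  if (is.null(ihc_pattern)) {
    ihc_pattern <- setNames(
      rep(list(list(probs = c(0, 0, 1, 0), normal = "medium")), length(genes)),
      genes
    )
  }
  for (g in names(ihc_pattern)) {
    pat <- ihc_pattern[[g]]
    if (is.null(pat)) next
    if (length(pat$probs) != 4 || any(pat$probs < 0) ||
        abs(sum(pat$probs) - 1) > 1e-8) {
      rlang::abort(paste0("ihc_pattern probabilities for ", g, " must be 4 non-negative values summing to 1."))
    }
    if (!pat$normal %in% ihc_levels) {
      rlang::abort(paste0("ihc_pattern normal level for ", g, " must be one of: ",
                          paste(ihc_levels, collapse = ", ")))
    }
  }
  structure(
    list(
      genes = genes, n_tumor = n_tumor, n_normal = n_normal,
      baseline_mean = baseline_mean, dispersion = dispersion,
      planted_log2fc = planted_log2fc, library_size_sd = library_size_sd,
      gene_factor_sd = gene_factor_sd, fpkm_map = fpkm_map,
      ihc_pattern = ihc_pattern, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a negative-binomial tumor/normal count matrix
#'
#' Draws counts `NB(mean = baseline * 2^(planted_log2fc * is_tumor) *
#' library_factor * gene_sample_factor, dispersion)` per gene and sample, and
#' returns the raw counts alongside the planted ground truth. Dispersion zero
#' degenerates to Poisson. All randomness derives from `config$seed`; the
#' global RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (tibble, gene column + samples), `meta`
#'   (tibble `sample_id`, `condition`), `truth` (tibble `gene`,
#'   `true_log2fc`, `true_dispersion`) and `gene_factors` (tibble of the
#'   gene-by-sample technical factors actually used).
#' @examples
#' sim <- simulate_counts(sim_config(n_tumor = 3, n_normal = 3, seed = 7))
#' sim$counts[1:3, 1:4]
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ng <- length(config$genes)
    ns <- config$n_tumor + config$n_normal
    sample_id <- c(
      sprintf("tumor_%02d", seq_len(config$n_tumor)),
      sprintf("normal_%02d", seq_len(config$n_normal))
    )
    condition <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
    lib <- exp(stats::rnorm(ns, 0, config$library_size_sd))
    gsf <- matrix(exp(stats::rnorm(ng * ns, 0, config$gene_factor_sd)), ng, ns)
    is_tumor <- as.numeric(condition == "tumor")
    mu <- config$baseline_mean *
      2^(outer(config$planted_log2fc, is_tumor)) *
      matrix(lib, ng, ns, byrow = TRUE) * gsf
    alpha <- config$dispersion
    counts <- matrix(0, ng, ns)
    for (g in seq_len(ng)) {
      counts[g, ] <- if (alpha[g] < 1e-12) {
        stats::rpois(ns, mu[g, ])
      } else {
        rnbinom(ns, mu = mu[g, ], size = 1 / alpha[g])
      }
    }
    tib <- function(m) {
      out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
      names(out) <- sample_id
      tibble::add_column(out, gene = config$genes, .before = 1)
    }
    list(
      counts = tib(counts),
      meta = tibble::tibble(sample_id = sample_id, condition = condition),
      truth = tibble::tibble(
        gene = config$genes,
        true_log2fc = unname(config$planted_log2fc),
        true_dispersion = unname(config$dispersion)
      ),
      gene_factors = tib(gsf)
    )
  })
}

#' Simulate multinomial IHC staining tallies
#'
#' For each gene with an IHC pattern, draws the staining level of each of
#' `n_tumor` tumor samples from the gene's multinomial level distribution and
#' tallies them; the assigned normal level is copied from the pattern. Genes
#' whose pattern is `NULL` are emitted with zero tallies and a missing normal
#' level — the "no IHC performed" case.
#'
#' @param config A [sim_config()].
#' @param cancer Cancer label attached to every record (default `"study"`).
#' @return A tally tibble suitable for [score_ihc()].
#' @export
simulate_ihc <- function(config, cancer = "study") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    rows <- purrr::map(names(config$ihc_pattern), function(g) {
      pat <- config$ihc_pattern[[g]]
      if (is.null(pat)) {
        n <- c(0L, 0L, 0L, 0L)
        normal <- NA_character_
      } else {
        n <- as.integer(rmultinom(1, config$n_tumor, pat$probs)[, 1])
        normal <- pat$normal
      }
      tibble::tibble(
        gene = g, cancer = cancer,
        n_not_detected = n[1], n_low = n[2], n_medium = n[3], n_high = n[4],
        normal_level = normal
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Per-gene average FPKM table of a simulated cohort
#'
#' @param config A [sim_config()]; the FPKM values are the configured
#'   `fpkm_map` (the generator treats average FPKM as a design parameter, not
#'   a resampled quantity).
#' @return A tibble with columns `gene` and `fpkm`.
#' @export
simulate_fpkm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble::tibble(gene = config$genes, fpkm = unname(config$fpkm_map))
}

#' Build a self-consistent miniature demo study
#'
#' Generates a complete single-cancer input bundle — raw counts, sample
#' metadata, FPKM table, IHC tallies and the pairing rules — with a known
#' planted truth, so the end-to-end pipeline has a deterministic expected
#' output. By default `ITGA6` and `ITGB4` are planted overexpressed (log2
#' fold change 2, 50 tumor vs 50 normal samples, average FPKM 50) at both the
#' RNA and the protein level, while every other subunit is null with FPKM 5;
#' the planted truth then forces the strict heterodimer call to be exactly
#' the a6b4 receptor. `ITGA4` and `ITGA10` carry no IHC data, as in public
#' pathology atlases.
#'
#' @param seed Integer seed.
#' @param plant Character vector of subunit genes to overexpress.
#' @param planted_log2fc Planted RNA effect size (default 2).
#' @param n_tumor,n_normal Cohort sizes (default 50/50).
#' @param planted_fpkm,background_fpkm Average FPKM for planted and background
#'   genes (defaults 50 and 5).
#' @param cancer Cancer label (default `"DEMO"`).
#' @param outdir Optional directory; when given, the bundle is written as
#'   `counts.tsv`, `meta.tsv`, `fpkm.tsv`, `ihc.tsv` and `pairing_rules.tsv`.
#' @return A list with `counts`, `meta`, `fpkm`, `ihc`, `rules`, `truth` and
#'   the `config` used.
#' @examples
#' demo <- make_demo_study(seed = 1)
#' names(demo)
#' @export
make_demo_study <- function(seed = 1L, plant = c("ITGA6", "ITGB4"),
                            planted_log2fc = 2, n_tumor = 50, n_normal = 50,
                            planted_fpkm = 50, background_fpkm = 5,
                            cancer = "DEMO", outdir = NULL) {
  catalog <- load_catalog()
  plant <- check_pass_set(plant, catalog)
  genes <- catalog$gene
  no_ihc <- c("ITGA4", "ITGA10")
  pattern <- setNames(lapply(genes, function(g) {
    if (g %in% no_ihc) {
      NULL
    } else if (g %in% plant) {
      list(probs = c(0, 0.05, 0.15, 0.80), normal = "low")
    } else {
      list(probs = c(0, 0, 1, 0), normal = "medium")
    }
  }), genes)
  config <- sim_config(
    genes = genes, n_tumor = n_tumor, n_normal = n_normal,
    planted_log2fc = setNames(rep(planted_log2fc, length(plant)), plant),
    fpkm_map = setNames(
      ifelse(genes %in% plant, planted_fpkm, background_fpkm), genes
    ),
    ihc_pattern = pattern, seed = seed
  )
  sim <- simulate_counts(config)
  bundle <- list(
    counts = sim$counts,
    meta = sim$meta,
    fpkm = simulate_fpkm(config),
    ihc = simulate_ihc(config, cancer = cancer),
    rules = load_pairing_rules(catalog = catalog),
    truth = sim$truth,
    config = config
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(bundle$counts, file.path(outdir, "counts.tsv"))
    readr::write_tsv(bundle$meta, file.path(outdir, "meta.tsv"))
    readr::write_tsv(bundle$fpkm, file.path(outdir, "fpkm.tsv"))
    readr::write_tsv(bundle$ihc, file.path(outdir, "ihc.tsv"))
    readr::write_tsv(bundle$rules, file.path(outdir, "pairing_rules.tsv"))
  }
  bundle
}
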