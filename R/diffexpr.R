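#' @importFrom rlang .data
#' @importFrom stats median pnorm rnbinom rmultinom var setNames
NULL

# counts tibble (gene column + one column per sample) -> validated numeric matrix
as_count_matrix <- function(counts, gene_col = "gene") {
  if (!gene_col %in% names(counts)) {
    rlang::abort(paste0("Counts table has no '", gene_col, "' column."))
  }
  genes <- as.character(counts[[gene_col]])
  if (anyDuplicated(genes)) {
    rlang::abort("Counts table has duplicated gene symbols.")
  }
  m <- as.matrix(counts[setdiff(names(counts), gene_col)])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) {
    rlang::abort("Counts must be non-negative and complete.")
  }
  rownames(m) <- genes
  m
}

check_meta <- function(meta, sample_ids) {
  if (!all(c("sample_id", "condition") %in% names(meta))) {
    rlang::abort("Metadata must have columns 'sample_id' and 'condition'.")
  }
  if (!all(meta$condition %in% c("tumor", "normal"))) {
    rlang::abort("Metadata condition must be 'tumor' or 'normal'.")
  }
  if (!setequal(meta$sample_id, sample_ids)) {
    rlang::abort("Metadata sample_id set does not match the counts columns.")
  }
  meta <- meta[match(sample_ids, meta$sample_id), ]
  tab <- table(meta$condition)
  if (length(tab) < 2 || any(tab < 2)) {
    rlang::abort("At least 2 samples per condition (tumor and normal) are required.")
  }
  meta
}

geomean <- function(x) exp(mean(log(x)))

#' Median-of-ratios size factors
#'
#' Estimates per-sample sequencing-depth factors from a raw count table with
#' the median-of-ratios estimator: each count is divided by its gene's
#' geometric mean across samples, and a sample's factor is the median of those
#' ratios over genes counted in every sample.
#'
#' @param counts Tibble/data frame of raw counts: a gene-symbol column plus
#'   one numeric column per sample.
#' @param gene_col Name of the gene column (default `"gene"`).
#'
#' @return A tibble with columns `sample_id` and `size_factor` (all positive).
#' @examples
#' demo <- make_demo_study(seed = 1)
#' size_factors(demo$counts)
#' @export
size_factors <- function(counts, gene_col = "gene") {
  m <- as_count_matrix(counts, gene_col)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    rlang::abort(paste0(
      "No gene has nonzero counts in every sample; median-of-ratios is ",
      "undefined. Consider a pseudo-reference (e.g. add genes or pool samples)."
    ))
  }
  ref <- apply(m[keep, , drop = FALSE], 1, geomean)
  sf <- apply(m[keep, , drop = FALSE] / ref, 2, median)
  tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Gene-by-sample normalization factor matrix
#'
#' Builds the full normalization factor matrix used as a GLM offset in the
#' differential expression test. An optional externally supplied gene-by-sample
#' factor matrix (e.g. GC-content/length bias factors) is first rescaled so
#' that each gene's row has geometric mean exactly 1 — this keeps normalized
#' counts on the scale of the raw counts — and is then multiplied column-wise
#' by the median-of-ratios size factors.
#'
#' @param counts Raw count tibble (see [size_factors()]).
#' @param gene_factors Optional tibble/matrix of positive gene-by-sample
#'   factors with the same genes and samples as `counts`; `NULL` means no
#'   gene-level bias correction (all ones).
#' @param gene_col Name of the gene column.
#'
#' @return A tibble shaped like `counts` holding the full factors, with
#'   attributes `size_factors` (named per-sample vector) and `gene_component`
#'   (the rescaled gene-level matrix, every row geometric mean 1).
#' @export
normalization_factors <- function(counts, gene_factors = NULL, gene_col = "gene") {
  m <- as_count_matrix(counts, gene_col)
  sf <- size_factors(counts, gene_col)
  sfv <- setNames(sf$size_factor, sf$sample_id)
  if (is.null(gene_factors)) {
    gf <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    if (is.data.frame(gene_factors)) {
      gf <- as.matrix(gene_factors[setdiff(names(gene_factors), gene_col)])
      rownames(gf) <- as.character(gene_factors[[gene_col]])
    } else {
      gf <- as.matrix(gene_factors)
      if (is.null(rownames(gf))) rownames(gf) <- rownames(m)
    }
    if (!identical(dim(gf), dim(m))) {
      rlang::abort("gene_factors must have the same dimensions as the counts.")
    }
    gf <- gf[rownames(m), colnames(m), drop = FALSE]
    if (any(gf <= 0) || anyNA(gf)) {
      rlang::abort("gene_factors must be strictly positive.")
    }
  }
  gf <- gf / apply(gf, 1, geomean)
  full <- sweep(gf, 2, sfv[colnames(gf)], `*`)
  out <- tibble::as_tibble(full)
  out <- tibble::add_column(out, gene = rownames(m), .before = 1)
  names(out)[1] <- gene_col
  attr(out, "size_factors") <- sfv
  attr(out, "gene_component") <- gf
  out
}

#' Per-gene negative-binomial dispersion, method of moments
#'
#' Estimates the NB dispersion \eqn{\alpha} (variance \eqn{\mu + \alpha\mu^2})
#' per gene from normalized counts: within each condition the moment estimator
#' \eqn{\max(0, (s^2 - \bar m)/\bar m^2)} is computed and the two condition
#' estimates are averaged, with a floor of 1e-8. Genes with zero counts in
#' every sample have no defined dispersion and are returned as `NA` (they are
#' not testable).
#'
#' @param counts Raw count tibble.
#' @param meta Sample metadata tibble (`sample_id`, `condition`).
#' @param norm Normalization factor tibble from [normalization_factors()];
#'   computed from `counts` when `NULL`.
#' @param gene_col Name of the gene column.
#'
#' @return A tibble with columns `gene` and `dispersion`.
#' @export
estimate_dispersion <- function(counts, meta, norm = NULL, gene_col = "gene") {
  m <- as_count_matrix(counts, gene_col)
  meta <- check_meta(meta, colnames(m))
  if (is.null(norm)) norm <- normalization_factors(counts, gene_col = gene_col)
  nf <- as_count_matrix(norm, gene_col)[rownames(m), colnames(m), drop = FALSE]
  y <- m / nf
  disp <- vapply(seq_len(nrow(m)), function(g) {
    if (all(m[g, ] == 0)) {
      return(NA_real_)
    }
    per_cond <- vapply(c("tumor", "normal"), function(cond) {
      yg <- y[g, meta$condition == cond]
      mbar <- mean(yg)
      if (mbar <= 0) {
        return(NA_real_)
      }
      max(0, (var(yg) - mbar) / mbar^2)
    }, numeric(1))
    per_cond <- per_cond[!is.na(per_cond)]
    max(mean(per_cond), 1e-8)
  }, numeric(1))
  tibble::tibble(gene = rownames(m), dispersion = disp)
}

# IRLS for one gene: log-link NB GLM with fixed dispersion,
# design (intercept, tumor indicator), log-normalization-factor offset.
# Coefficients are capped at |beta| <= cap (natural-log scale) and the
# normal-equation matrix gets a small ridge, so genes expressed in only one
# condition still return finite estimates.
fit_nb_gene <- function(y, is_tumor, off, alpha, cap = 20, ridge = 1e-8,
                        maxit = 100, tol = 1e-8) {
  X <- cbind(1, is_tumor)
  beta <- c(log(max(mean(y / exp(off)), 1e-8)), 0)
  delta <- Inf
  A <- NULL
  for (it in seq_len(maxit)) {
    eta <- off + as.vector(X %*% beta)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + diag(ridge, 2)
    beta_new <- as.vector(solve(A, XtW %*% z))
    beta_new <- pmin(pmax(beta_new, -cap), cap)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  eta <- off + as.vector(X %*% beta)
  mu <- pmax(exp(eta), 1e-10)
  w <- mu / (1 + alpha * mu)
  A <- t(X * w) %*% X + diag(ridge, 2)
  se <- sqrt(solve(A)[2, 2])
  list(beta = beta, se = se, converged = delta < tol || abs(beta[2]) >= cap)
}

#' Negative-binomial Wald test for tumor vs normal differential expression
#'
#' Fits, per gene, a log-linear negative-binomial model with a tumor/normal
#' indicator and the log normalization factors as offset, holding the per-gene
#' dispersion fixed, and tests the tumor coefficient with a Wald z statistic
#' (two-sided normal p-value). The reported `log2fc` is the unshrunk tumor
#' coefficient on the log2 scale; positive values mean higher expression in
#' tumor samples. P-values are adjusted across tested genes with the
#' Benjamini-Hochberg procedure ([bh_adjust()]).
#'
#' Genes with zero counts in every sample are reported untested
#' (`tested = FALSE`, missing statistics). A gene expressed in only one
#' condition still gets a finite estimate through the coefficient cap
#' (|beta| <= 20 on the natural-log scale) and ridge guard of the fitter;
#' a gene whose fit fails to converge is marked untested with a warning,
#' never an error.
#'
#' @param counts Raw count tibble (gene column + sample columns).
#' @param meta Sample metadata tibble with `sample_id` and
#'   `condition` in `{"tumor", "normal"}`; at least 2 samples per condition.
#' @param norm Normalization factors from [normalization_factors()];
#'   recomputed when `NULL`.
#' @param dispersion Per-gene dispersion tibble from [estimate_dispersion()];
#'   recomputed when `NULL`.
#' @param gene_col Name of the gene column.
#'
#' @return A tibble with one row per gene: `gene`, `log2fc`, `pvalue`, `fdr`,
#'   `mean_normalized_count`, `tested`.
#' @examples
#' demo <- make_demo_study(seed = 1)
#' de <- nb_wald_test(demo$counts, demo$meta)
#' dplyr::filter(de, fdr < 0.05)
#' @export
nb_wald_test <- function(counts, meta, norm = NULL, dispersion = NULL,
                         gene_col = "gene") {
  m <- as_count_matrix(counts, gene_col)
  meta <- check_meta(meta, colnames(m))
  if (is.null(norm)) norm <- normalization_factors(counts, gene_col = gene_col)
  nf <- as_count_matrix(norm, gene_col)[rownames(m), colnames(m), drop = FALSE]
  if (any(nf <= 0)) rlang::abort("Normalization factors must be positive.")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, meta, norm, gene_col = gene_col)
  }
  disp <- setNames(dispersion$dispersion, dispersion$gene)[rownames(m)]
  is_tumor <- as.numeric(meta$condition == "tumor")

  res <- purrr::map(seq_len(nrow(m)), function(g) {
    y <- m[g, ]
    base <- tibble::tibble(
      gene = rownames(m)[g], log2fc = NA_real_, pvalue = NA_real_,
      mean_normalized_count = mean(y / nf[g, ]), tested = FALSE
    )
    if (all(y == 0) || is.na(disp[g])) {
      return(base)
    }
    fit <- tryCatch(
      fit_nb_gene(y, is_tumor, log(nf[g, ]), disp[g]),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || !is.finite(fit$se)) {
      rlang::warn(paste0("NB fit did not converge for gene ", rownames(m)[g], "; marked untested."))
      return(base)
    }
    z <- fit$beta[2] / fit$se
    base$log2fc <- fit$beta[2] / log(2)
    base$pvalue <- 2 * pnorm(-abs(z))
    base$tested <- TRUE
    base
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- bh_adjust(out$pvalue)
  out[c("gene", "log2fc", "pvalue", "fdr", "mean_normalized_count", "tested")]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Missing values pass through as
#' missing and do not count toward the number of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Numeric vector of BH-adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Fit the full tumor-vs-normal differential expression model
#'
#' Convenience wrapper running the whole RNA stage: size factors,
#' normalization factor matrix (optionally with supplied gene-level bias
#' factors), method-of-moments dispersions, per-gene NB Wald tests and BH
#' adjustment. Returns a fitted object with [generics::tidy()] /
#' [generics::glance()] methods and an [ggplot2::autoplot()] volcano display.
#'
#' @inheritParams nb_wald_test
#' @param gene_factors Optional gene-by-sample bias factor table passed to
#'   [normalization_factors()].
#' @return An object of class `nb_de`.
#' @examples
#' demo <- make_demo_study(seed = 1)
#' fit <- nb_de(demo$counts, demo$meta)
#' glance(fit)
#' @export
nb_de <- function(counts, meta, gene_factors = NULL, gene_col = "gene") {
  m <- as_count_matrix(counts, gene_col)
  meta <- check_meta(meta, colnames(m))
  norm <- normalization_factors(counts, gene_factors, gene_col = gene_col)
  dispersion <- estimate_dispersion(counts, meta, norm, gene_col = gene_col)
  results <- nb_wald_test(counts, meta, norm, dispersion, gene_col = gene_col)
  structure(
    list(
      results = results,
      dispersion = dispersion,
      size_factors = attr(norm, "size_factors"),
      n_tumor = sum(meta$condition == "tumor"),
      n_normal = sum(meta$condition == "normal")
    ),
    class = "nb_de"
  )
}

#' @export
print.nb_de <- function(x, ...) {
  cat("Negative-binomial tumor-vs-normal differential expression fit\n")
  cat("  genes:", nrow(x$results),
      " tested:", sum(x$results$tested),
      " fdr<0.05:", sum(x$results$fdr < 0.05, na.rm = TRUE), "\n")
  cat("  samples:", x$n_tumor, "tumor /", x$n_normal, "normal\n")
  invisible(x)
}
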