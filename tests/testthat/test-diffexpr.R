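test_that("size factors recover exact library scalings", {
  base <- c(10, 100, 40, 7, 250)
  counts <- tibble::tibble(
    gene = paste0("G", 1:5),
    s1 = base, s2 = 2 * base, s3 = 4 * base
  )
  sf <- size_factors(counts)
  expect_equal(sf$size_factor / sf$size_factor[1], c(1, 2, 4))
  # identical columns give unit factors
  same <- tibble::tibble(gene = paste0("G", 1:5), a = base, b = base, c = base)
  expect_equal(size_factors(same)$size_factor, rep(1, 3))
})

test_that("size factors agree with an independent median-of-ratios oracle", {
  sim <- random_sim(n_genes = 50, n_tumor = 4, n_normal = 4, seed = 5,
                    library_size_sd = 0.3)
  m <- as.matrix(sim$counts[-1])
  sf <- size_factors(sim$counts)
  expect_equal(sf$size_factor, unname(sf_brute(m)), tolerance = 1e-12)
})

test_that("size factors error when no gene covers all samples", {
  counts <- tibble::tibble(gene = c("G1", "G2"), a = c(0, 5), b = c(5, 0))
  expect_error(size_factors(counts), "pseudo-reference")
})

test_that("normalization matrix rescales gene rows to geometric mean 1", {
  counts <- tiny_counts()
  # default (all-ones) gene component: rows equal the size-factor vector
  nf <- normalization_factors(counts)
  sf <- size_factors(counts)
  for (i in seq_len(nrow(counts))) {
    expect_equal(unlist(nf[i, -1], use.names = FALSE), sf$size_factor)
  }
  # supplied constant row collapses to ones
  gf <- counts
  gf[-1] <- 2
  nf2 <- normalization_factors(counts, gene_factors = gf)
  expect_equal(attr(nf2, "gene_component")[1, ], rep(1, 6), ignore_attr = TRUE)
  # random positive factors: every gene-level row has geomean 1 +- 1e-8
  set.seed(42)
  gf[-1] <- matrix(exp(rnorm(36, 0, 0.5)), 6, 6)
  nf3 <- normalization_factors(counts, gene_factors = gf)
  gc <- attr(nf3, "gene_component")
  expect_true(all(abs(apply(gc, 1, function(x) exp(mean(log(x)))) - 1) < 1e-8))
  gf[2, 3] <- -1
  expect_error(normalization_factors(counts, gene_factors = gf), "positive")
})

test_that("dispersion estimation hits the floor for Poisson-like and constant genes", {
  sim <- random_sim(n_genes = 30, n_tumor = 150, n_normal = 150, seed = 3,
                    dispersion = 0, library_size_sd = 0)
  disp <- estimate_dispersion(sim$counts, sim$meta)
  # Poisson limit: variance = mean, so the NB alpha estimate collapses
  expect_lt(mean(disp$dispersion), 0.01)
  const <- tibble::tibble(gene = "G1", t1 = 5, t2 = 5, n1 = 5, n2 = 5)
  meta <- tibble::tibble(sample_id = c("t1", "t2", "n1", "n2"),
                         condition = c("tumor", "tumor", "normal", "normal"))
  expect_equal(estimate_dispersion(const, meta)$dispersion, 1e-8)
})

test_that("dispersion estimation recovers a planted NB alpha", {
  sim <- random_sim(n_genes = 60, n_tumor = 200, n_normal = 200, seed = 8,
                    dispersion = 0.2, library_size_sd = 0)
  disp <- estimate_dispersion(sim$counts, sim$meta)
  expect_gt(mean(disp$dispersion), 0.15)
  expect_lt(mean(disp$dispersion), 0.25)
})

test_that("all-zero genes are undispersed and untested", {
  counts <- tiny_counts() # G3 is all zero
  de <- nb_wald_test(counts, tiny_meta())
  expect_false(de$tested[de$gene == "G3"])
  expect_true(is.na(de$log2fc[de$gene == "G3"]))
  expect_true(is.na(de$fdr[de$gene == "G3"]))
  disp <- estimate_dispersion(counts, tiny_meta())
  expect_true(is.na(disp$dispersion[disp$gene == "G3"]))
})

test_that("the Wald fit matches an independent NB GLM oracle", {
  skip_if_not_installed("MASS")
  sim <- random_sim(n_genes = 20, n_tumor = 30, n_normal = 30, seed = 17,
                    dispersion = 0.1,
                    planted_log2fc = stats::setNames(rep(1.5, 5), sprintf("g%03d", 1:5)))
  norm <- normalization_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sim$meta, norm)
  de <- nb_wald_test(sim$counts, sim$meta, norm, disp)
  nf <- as.matrix(norm[-1])
  m <- as.matrix(sim$counts[-1])
  is_tumor <- as.numeric(sim$meta$condition == "tumor")
  for (g in c(1, 3, 7, 15)) {
    fit <- stats::glm(
      m[g, ] ~ is_tumor + offset(log(nf[g, ])),
      family = MASS::negative.binomial(theta = 1 / disp$dispersion[g])
    )
    expect_equal(de$log2fc[g], unname(stats::coef(fit)[2]) / log(2),
                 tolerance = 1e-4)
    se_log2fc <- sqrt(stats::vcov(fit)[2, 2]) / log(2)
    z_oracle <- (unname(stats::coef(fit)[2]) / log(2)) / se_log2fc
    expect_equal(de$pvalue[g], 2 * stats::pnorm(-abs(z_oracle)), tolerance = 5e-3)
  }
})

test_that("log2fc sign convention: positive means higher in tumor", {
  sim <- random_sim(
    n_genes = 10, n_tumor = 40, n_normal = 40, seed = 21,
    planted_log2fc = stats::setNames(c(2, -2), c("g001", "g002"))
  )
  de <- nb_wald_test(sim$counts, sim$meta)
  expect_gt(de$log2fc[de$gene == "g001"], 1)
  expect_lt(de$log2fc[de$gene == "g002"], -1)
})

test_that("rescaling one sample's counts moves size factors, not fold changes", {
  sim <- random_sim(n_genes = 80, n_tumor = 10, n_normal = 10, seed = 31)
  de1 <- nb_wald_test(sim$counts, sim$meta)
  scaled <- sim$counts
  scaled[["tumor_01"]] <- round(scaled[["tumor_01"]] * 3)
  sf2 <- size_factors(scaled)
  expect_equal(sf2$size_factor[sf2$sample_id == "tumor_01"] /
                 size_factors(sim$counts)$size_factor[1], 3, tolerance = 0.1)
  de2 <- nb_wald_test(scaled, sim$meta)
  # rounding perturbs individual genes slightly; the estimates stay centred
  expect_equal(mean(de2$log2fc - de1$log2fc), 0, tolerance = 0.05)
})

test_that("with vanishing dispersion the Wald p agrees with a Poisson GLM", {
  sim <- random_sim(n_genes = 15, n_tumor = 100, n_normal = 100, seed = 41,
                    dispersion = 0, library_size_sd = 0)
  norm <- normalization_factors(sim$counts)
  de <- nb_wald_test(sim$counts, sim$meta, norm)
  m <- as.matrix(sim$counts[-1])
  nf <- as.matrix(norm[-1])
  is_tumor <- as.numeric(sim$meta$condition == "tumor")
  for (g in c(2, 9)) {
    pois <- stats::glm(m[g, ] ~ is_tumor + offset(log(nf[g, ])),
                       family = stats::poisson())
    p_pois <- 2 * stats::pnorm(-abs(stats::coef(pois)[2] /
                                      sqrt(stats::vcov(pois)[2, 2])))
    expect_equal(de$pvalue[g], unname(p_pois), tolerance = 0.1 * max(p_pois, 1e-10))
  }
})

test_that("a gene expressed in one condition only gets a finite capped estimate", {
  counts <- tiny_counts() # G6: zero in all normals
  de <- nb_wald_test(counts, tiny_meta())
  g6 <- de[de$gene == "G6", ]
  expect_true(g6$tested)
  expect_true(is.finite(g6$log2fc))
  expect_lte(abs(g6$log2fc), 20 / log(2) + 1e-9)
})

test_that("DE results keep fdr above pvalue and within [0, 1]", {
  sim <- random_sim(n_genes = 100, n_tumor = 8, n_normal = 8, seed = 51)
  de <- nb_wald_test(sim$counts, sim$meta)
  tested <- de[de$tested, ]
  expect_true(all(tested$fdr >= tested$pvalue - 1e-12))
  expect_true(all(tested$fdr <= 1))
  expect_true(all(tested$pvalue >= 0 & tested$pvalue <= 1))
})

test_that("DESeq2 broadly agrees on a strong planted effect", {
  skip_if_not_installed("DESeq2")
  demo <- make_demo_study(seed = 4)
  de <- nb_wald_test(demo$counts, demo$meta)
  m <- as.matrix(demo$counts[-1])
  rownames(m) <- demo$counts$gene
  storage.mode(m) <- "integer"
  coldata <- data.frame(condition = factor(demo$meta$condition,
                                           levels = c("normal", "tumor")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  for (g in c("ITGA6", "ITGB4")) {
    expect_equal(de$log2fc[de$gene == g], res[g, "log2FoldChange"],
                 tolerance = 0.1)
    expect_lt(res[g, "padj"], 0.05)
    expect_lt(de$fdr[de$gene == g], 0.05)
  }
})

test_that("input validation catches malformed counts and metadata", {
  counts <- tiny_counts()
  bad <- counts
  bad$t1[1] <- -1
  expect_error(nb_wald_test(bad, tiny_meta()), "non-negative")
  meta <- tiny_meta()
  meta$condition[1] <- "Tumour"
  expect_error(nb_wald_test(counts, meta), "tumor")
  expect_error(nb_wald_test(counts, tiny_meta()[-1, ]), "sample_id")
})
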