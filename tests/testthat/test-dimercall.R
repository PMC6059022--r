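test_that("strict calls require both subunits of an allowed pair", {
  expect_equal(call_strict(c("ITGA6", "ITGB4"))$name, "ITGA6/ITGB4")
  expect_equal(call_strict("ITGA6")$name, character(0)) # partners missing
  all27 <- load_catalog()$gene
  expect_equal(nrow(call_strict(all27)), 24)
  expect_error(call_strict("NOTAGENE"), "absent")
})

test_that("relaxed calls accept a single passing subunit and record the count", {
  b4 <- call_relaxed("ITGB4")
  expect_equal(b4$name, "ITGA6/ITGB4")
  expect_equal(b4$n_pass_subunits, 1L)
  av <- call_relaxed("ITGAV")
  expect_equal(nrow(av), 5) # the five alpha-v receptors
  expect_equal(nrow(call_relaxed("ITGBL1")), 0) # no partner exists
  both <- call_relaxed(c("ITGA6", "ITGB4"))
  expect_equal(both$n_pass_subunits[both$name == "ITGA6/ITGB4"], 2L)
  expect_equal(nrow(call_relaxed(load_catalog()$gene)), 24)
})

test_that("strict calls are a subset of relaxed calls for random pass sets", {
  genes <- load_catalog()$gene
  set.seed(33)
  for (i in 1:30) {
    pass <- sample(genes, sample(0:27, 1))
    s <- call_strict(pass)
    r <- call_relaxed(pass)
    expect_true(all(s$name %in% r$name))
    expect_true(all(r$name[r$n_pass_subunits == 2] %in% s$name))
    expect_setequal(s$name, r$name[r$n_pass_subunits == 2])
    expect_false("ITGBL1" %in% c(r$alpha_gene, r$beta_gene))
  }
})

test_that("the silent-partner expression requirement prunes relaxed calls", {
  # ITGAV passes; only ITGB6 among its partners is adequately expressed
  pruned <- call_relaxed("ITGAV", partner_ok = "ITGB6")
  expect_equal(pruned$name, "ITGAV/ITGB6")
  # two-subunit calls survive regardless of the partner list
  kept <- call_relaxed(c("ITGA6", "ITGB4"), partner_ok = character(0))
  expect_equal(kept$name[kept$n_pass_subunits == 2], "ITGA6/ITGB4")
})

test_that("evidence integration partitions the union of RNA and IHC calls", {
  ev <- integrate_evidence(c("ITGAV/ITGB6", "ITGA6/ITGB4"), "ITGAV/ITGB6")
  expect_equal(ev$evidence[ev$name == "ITGAV/ITGB6"], "both")
  expect_equal(ev$evidence[ev$name == "ITGA6/ITGB4"], "rna_only")
  set.seed(34)
  dimers <- enumerate_heterodimers()$name
  for (i in 1:25) {
    rna <- sample(dimers, sample(0:24, 1))
    ihc <- sample(dimers, sample(0:24, 1))
    ev <- integrate_evidence(rna, ihc)
    expect_setequal(ev$name, union(rna, ihc))
    expect_equal(
      sum(ev$evidence == "both") + sum(ev$evidence == "rna_only") +
        sum(ev$evidence == "ihc_only"),
      length(union(rna, ihc))
    )
    expect_setequal(ev$name[ev$evidence == "both"], intersect(rna, ihc))
    expect_setequal(ev$name[ev$evidence == "rna_only"], setdiff(rna, ihc))
  }
})

test_that("per-cancer calling combines RNA eligibility with IHC overexpression", {
  ranked <- tibble::tibble(
    cancer = c("PAAD", "PAAD", "GBM"),
    gene = c("ITGA6", "ITGB4", "ITGAV"),
    metric = c(2, 1.9, 1.2), log2fc = c(2, 1.9, 1.3),
    fdr = 0.01, fpkm = 50, fpkm_pass = TRUE, fpkm_borderline = FALSE,
    eligible = TRUE
  )
  ihc <- tibble::tibble(
    cancer = c("PAAD", "PAAD", "GBM"),
    gene = c("ITGA6", "ITGB4", "ITGB1"),
    weighted_average = 0.9, normal_value = 0.33,
    overexpressed = c(TRUE, TRUE, TRUE), reason = "overexpressed"
  )
  calls <- call_heterodimers(ranked, ihc, mode = "strict")
  paad <- calls[calls$cancer == "PAAD", ]
  expect_equal(paad$name, "ITGA6/ITGB4")
  expect_equal(paad$evidence, "both")
  # GBM: ITGAV eligible by RNA but alone -> no strict RNA call; IHC ITGB1 alone
  expect_equal(nrow(calls[calls$cancer == "GBM", ]), 0)
  relaxed <- call_heterodimers(ranked, ihc, mode = "relaxed")
  gbm <- relaxed[relaxed$cancer == "GBM", ]
  expect_equal(nrow(gbm), 5)
  expect_true(all(gbm$evidence == "rna_only"))
  expect_true(all(gbm$n_pass_subunits == 1L))
})
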