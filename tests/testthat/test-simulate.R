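test_that("simulation is deterministic under a fixed seed and leaves the RNG alone", {
  cfg <- sim_config(genes = letters[1:5], n_tumor = 4, n_normal = 4, seed = 42)
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  a <- simulate_counts(cfg)
  after <- runif(1)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(before, after) # global RNG stream untouched
  c2 <- simulate_counts(sim_config(genes = letters[1:5], n_tumor = 4,
                                   n_normal = 4, seed = 43))
  expect_false(identical(a$counts, c2$counts))
  expect_identical(a$truth, c2$truth) # planted labels do not depend on the seed
  expect_identical(simulate_ihc(cfg), simulate_ihc(cfg))
})

test_that("simulated counts match negative-binomial moments", {
  n <- 10000
  cfg <- sim_config(
    genes = "g1", n_tumor = n / 2, n_normal = n / 2,
    baseline_mean = 100, dispersion = 0.2, planted_log2fc = 0,
    library_size_sd = 0, seed = 5
  )
  y <- as.numeric(as.matrix(simulate_counts(cfg)$counts[-1]))
  expect_equal(mean(y), 100, tolerance = 0.02)
  expect_equal(var(y), 100 + 0.2 * 100^2, tolerance = 0.08)
  # Poisson degenerate case
  cfg0 <- sim_config(genes = "g1", n_tumor = n / 2, n_normal = n / 2,
                     baseline_mean = 50, dispersion = 0, library_size_sd = 0,
                     seed = 6)
  y0 <- as.numeric(as.matrix(simulate_counts(cfg0)$counts[-1]))
  expect_equal(var(y0) / mean(y0), 1, tolerance = 0.05)
})

test_that("planted fold changes scale the tumor means", {
  cfg <- sim_config(
    genes = c("up", "null"), n_tumor = 2000, n_normal = 2000,
    baseline_mean = 100, dispersion = 0.05,
    planted_log2fc = c(up = 2), library_size_sd = 0, seed = 7
  )
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$gene
  tum <- sim$meta$condition == "tumor"
  expect_equal(mean(m["up", tum]) / mean(m["up", !tum]), 4, tolerance = 0.1)
  expect_equal(mean(m["null", tum]) / mean(m["null", !tum]), 1, tolerance = 0.05)
  expect_equal(sim$truth$true_log2fc, c(2, 0))
})

test_that("simulated IHC tallies respect the configured patterns", {
  pattern <- list(
    hot = list(probs = c(0, 0, 0, 1), normal = "medium"),
    flat = list(probs = c(0, 0, 1, 0), normal = "medium"),
    missing = NULL
  )
  cfg <- sim_config(genes = names(pattern), n_tumor = 30, n_normal = 30,
                    ihc_pattern = pattern, seed = 9)
  tally <- simulate_ihc(cfg)
  sc <- score_ihc(tally)
  expect_true(sc$overexpressed[sc$gene == "hot"]) # all-high beats medium
  expect_false(sc$overexpressed[sc$gene == "flat"]) # exactly at normal level
  expect_equal(sc$reason[sc$gene == "missing"], "no_data")
  expect_equal(sum(tally[tally$gene == "hot", c("n_not_detected", "n_low",
                                                "n_medium", "n_high")]), 30)
  bad <- pattern
  bad$hot$probs <- c(0.5, 0, 0, 0.6)
  expect_error(sim_config(genes = names(bad), ihc_pattern = bad), "summing to 1")
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(genes = c("a", "a")), "duplicated|anyDuplicated")
  expect_error(sim_config(genes = "a", baseline_mean = -1), "positive")
  expect_error(sim_config(genes = "a", dispersion = -0.1), "non-negative")
  expect_error(sim_config(genes = "a", planted_log2fc = c(b = 2)), "Unknown gene")
  expect_error(sim_config(genes = "a", n_tumor = 0), "at least one")
})

test_that("the demo study carries a recoverable planted truth end to end", {
  demo <- make_demo_study(seed = 2)
  expect_setequal(
    demo$truth$gene[demo$truth$true_log2fc > 0], c("ITGA6", "ITGB4")
  )
  expect_equal(nrow(demo$counts), 27)
  expect_equal(nrow(demo$rules), 24)
  # no-IHC genes are encoded as missing data
  sc <- score_ihc(demo$ihc)
  expect_setequal(sc$gene[sc$reason == "no_data"], c("ITGA4", "ITGA10"))
  # writing the bundle round-trips through the TSV readers
  dir <- withr::local_tempdir()
  make_demo_study(seed = 2, outdir = dir)
  counts2 <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(as.matrix(counts2[-1]), as.matrix(demo$counts[-1]),
               ignore_attr = TRUE)
  expect_identical(read_meta(file.path(dir, "meta.tsv")), demo$meta)
})
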