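# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation.

# Step-up BH: adjusted_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(sorted[i:m] * m / (i:m))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# IHC weighted average by expanding the tally into individual samples.
wa_brute <- function(n_nd, n_lo, n_me, n_hi) {
  vals <- rep(c(0, 0.33, 0.66, 1), times = c(n_nd, n_lo, n_me, n_hi))
  mean(vals)
}

# Median-of-ratios size factors, written independently of the package.
sf_brute <- function(m) {
  keep <- apply(m, 1, function(x) all(x > 0))
  logref <- rowMeans(log(m[keep, , drop = FALSE]))
  apply(m[keep, , drop = FALSE], 2, function(col) {
    median(col / exp(logref))
  })
}

# A small deterministic count fixture: 6 genes x 6 samples.
tiny_counts <- function() {
  tibble::tibble(
    gene = paste0("G", 1:6),
    t1 = c(10, 100, 0, 55, 200, 7),
    t2 = c(12, 110, 0, 60, 190, 9),
    t3 = c(9, 95, 0, 50, 210, 6),
    n1 = c(11, 25, 0, 52, 205, 0),
    n2 = c(10, 30, 0, 58, 195, 0),
    n3 = c(12, 28, 0, 54, 200, 0)
  )
}

tiny_meta <- function() {
  tibble::tibble(
    sample_id = c("t1", "t2", "t3", "n1", "n2", "n3"),
    condition = rep(c("tumor", "normal"), each = 3)
  )
}

random_sim <- function(n_genes = 50, n_tumor = 8, n_normal = 8, seed = 99, ...) {
  simulate_counts(sim_config(
    genes = sprintf("g%03d", seq_len(n_genes)),
    n_tumor = n_tumor, n_normal = n_normal, seed = seed, ...
  ))
}
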