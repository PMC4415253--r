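# Shared fixtures, all built in code.

# Small deterministic genotype matrix with a known composition.
toy_genotypes <- function(n = 12, m = 5, seed = 7, missing = 0) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing > 0) d[sample(length(d), missing)] <- NA
  genotype_matrix(d)
}

# A small simulated dataset plus the shared estimation inputs, sized so the
# whole pipeline (REML, PEV, EM, Gibbs) runs in seconds.
toy_prep <- function(n = 400, m = 500, n_qtl = 15, h2 = 0.45, seed = 99) {
  counts <- c(5L, 5L, 5L)
  cfg <- sim_config(n_individuals = n, n_markers = m, n_qtl = n_qtl,
                    qtl_counts = counts, h2 = h2, seed = seed,
                    ref_fraction = 0.5)
  prepare_replicate(cfg)
}

# Memoised copy so several test files can share one build.
.toy_cache <- new.env(parent = emptyenv())
toy_prep_cached <- function() {
  if (is.null(.toy_cache$prep)) .toy_cache$prep <- toy_prep()
  .toy_cache$prep
}

expect_simplex <- function(x, tol = 1e-10) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = 1e-8)
}
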