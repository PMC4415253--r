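test_that("sim_config validates its fields", {
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(n_qtl = 60, n_markers = 50), "n_qtl")
  expect_error(sim_config(qtl_counts = c(10, 10, 10), n_qtl = 50), "sum")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
})

test_that("genotype simulation is deterministic and respects the MAF floor", {
  cfg <- sim_config(n_individuals = 300, n_markers = 200, n_qtl = 10,
                    qtl_counts = c(4L, 3L, 3L), seed = 5, maf_floor = 0.05)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  # configured spectrum never goes below the floor; realized frequencies can
  # undershoot only by sampling noise
  p <- allele_frequencies(g1)
  expect_gt(min(pmin(p, 1 - p)), 0.05 - 3 * sqrt(0.05 * 0.95 / (2 * 300)))
})

test_that("ld_decay = 0 gives uncorrelated adjacent markers", {
  cfg <- sim_config(n_individuals = 4000, n_markers = 60, n_qtl = 5,
                    qtl_counts = c(2L, 2L, 1L), ld_decay = 0, seed = 8)
  d <- simulate_genotypes(cfg)$dosages
  r <- sapply(seq_len(59), function(j) cor(d[, j], d[, j + 1]))
  expect_lt(max(abs(r)), 0.05)
})

test_that("positive ld_decay induces adjacent-marker correlation", {
  cfg <- sim_config(n_individuals = 4000, n_markers = 60, n_qtl = 5,
                    qtl_counts = c(2L, 2L, 1L), ld_decay = 0.8, seed = 8)
  d <- simulate_genotypes(cfg)$dosages
  r <- sapply(seq_len(59), function(j) cor(d[, j], d[, j + 1]))
  expect_gt(mean(r), 0.3)
})

test_that("mixture QTL effects produce the analytic genetic variance", {
  # expected var(TBV) = 17 * 0.0006 + 16 * 0.006 + 17 * 0.06 = 1.1262;
  # check the mean realized variance over replicates against it
  vars <- vapply(1:200, function(s) {
    cfg <- sim_config(n_individuals = 2, n_markers = 100, n_qtl = 50,
                      qtl_counts = c(17L, 16L, 17L), seed = s)
    q <- assign_qtl_effects(cfg, structure(list(m = 100L),
                                           class = "genotype_matrix"))
    sum(q$qtl_effects^2)   # orthonormal-column limit of var(Z g)
  }, numeric(1))
  expect_equal(mean(vars), 1.1262, tolerance = 0.05)
})

test_that("single-normal architecture spreads sigma_g2 over the QTL", {
  cfg <- sim_config(architecture = "single_normal", n_individuals = 2,
                    n_markers = 100, n_qtl = 50, seed = 1)
  effs <- replicate(300, {
    cfg$seed <- cfg$seed + 1L
    assign_qtl_effects(cfg, structure(list(m = 100L),
                                      class = "genotype_matrix"))$qtl_effects
  })
  expect_equal(mean(effs^2), 1 / 50, tolerance = 0.05)
})

test_that("no QTL means a flat trait", {
  cfg <- sim_config(n_individuals = 50, n_markers = 40, n_qtl = 0,
                    qtl_counts = c(0L, 0L, 0L), seed = 3)
  rep <- simulate_replicate(cfg)
  expect_true(all(rep$tbv == 0))
})

test_that("residual variance follows the heritability identity", {
  cfg <- sim_config(n_individuals = 2000, n_markers = 150, n_qtl = 12,
                    qtl_counts = c(4L, 4L, 4L), h2 = 0.45, seed = 21)
  rep <- simulate_replicate(cfg)
  expect_equal(rep$sigma_e2_used,
               var(rep$tbv) * (1 - 0.45) / 0.45, tolerance = 1e-12)
  # regression of y on tbv has slope about 1
  expect_equal(unname(coef(lm(rep$phenotypes ~ rep$tbv))[2]), 1,
               tolerance = 0.06)
  # realized heritability near the configured value
  expect_equal(var(rep$tbv) / var(rep$phenotypes), 0.45, tolerance = 0.05)
})

test_that("reference/validation split follows the heritability convention", {
  cfg45 <- sim_config(h2 = 0.45, seed = 1)
  s45 <- split_reference_validation(cfg45, 5000)
  expect_length(s45$reference, 2500)
  expect_length(s45$validation, 2500)
  cfg10 <- sim_config(h2 = 0.10, seed = 1)
  s10 <- split_reference_validation(cfg10, 5000)
  expect_length(s10$reference, 3750)
  expect_length(s10$validation, 1250)
  expect_length(intersect(s10$reference, s10$validation), 0)
  expect_setequal(c(s10$reference, s10$validation), 1:5000)
  # other heritabilities use the supplied fraction
  cfg30 <- sim_config(h2 = 0.30, ref_fraction = 0.6, seed = 1)
  expect_length(split_reference_validation(cfg30, 100)$reference, 60)
})

test_that("a replicate is a pure function of its seed", {
  cfg <- sim_config(n_individuals = 150, n_markers = 60, n_qtl = 6,
                    qtl_counts = c(2L, 2L, 2L), seed = 77, maf_floor = 0.1)
  r1 <- simulate_replicate(cfg)
  r2 <- simulate_replicate(cfg)
  expect_identical(r1$genotypes$dosages, r2$genotypes$dosages)
  expect_identical(r1$qtl_idx, r2$qtl_idx)
  expect_equal(r1$phenotypes, r2$phenotypes)
  expect_identical(r1$reference, r2$reference)
})

test_that("replicates write out as consistent plain-text files", {
  cfg <- sim_config(n_individuals = 20, n_markers = 15, n_qtl = 3,
                    qtl_counts = c(1L, 1L, 1L), seed = 12)
  rep <- simulate_replicate(cfg)
  dir <- withr::local_tempdir()
  write_replicate(rep, dir)
  g <- read_dosage_tsv(file.path(dir, "dosages.tsv"))
  expect_identical(g$dosages, rep$genotypes$dosages)
  y <- read_phenotype_tsv(file.path(dir, "phenotypes.tsv"), genotypes = g)
  expect_equal(unname(y), rep$phenotypes, tolerance = 1e-12)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(truth$true_effect[rep$qtl_idx], rep$qtl_effects,
               tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "config.json")))
})
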