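#' Configuration for a simulated quantitative-trait dataset
#'
#' Describes one synthetic genotype/phenotype replicate: a marker panel with
#' a neutral-like allele-frequency spectrum and first-order linkage along
#' the panel, a set of QTL hidden among the genotyped markers, and
#' phenotypes formed by adding normal residuals to the true breeding values
#' at a chosen heritability. Defaults correspond to the 10 K benchmark
#' architecture used throughout the package: 5000 individuals, 10 050
#' markers of which 50 are QTL, and for the mixture architecture 17/16/17
#' QTL effects drawn from N(0, 0.0006 sigma_g2), N(0, 0.006 sigma_g2) and
#' N(0, 0.06 sigma_g2) so the expected genetic variance is close to
#' `sigma_g2`.
#'
#' @param n_individuals Number of individuals (default 5000).
#' @param n_markers Number of markers including the QTL (default 10050).
#' @param n_qtl Number of QTL (default 50).
#' @param qtl_counts Integer triple giving how many QTL fall in each of the
#'   three non-null effect-variance classes of the mixture architecture
#'   (default `c(17, 16, 17)`; must sum to `n_qtl`).
#' @param architecture `"mixture"` (three-class effects) or
#'   `"single_normal"` (all QTL effects from one N(0, sigma_g2 / n_qtl)).
#' @param h2 Trait heritability in (0, 1).
#' @param sigma_g2 Target genetic variance on the standardized-genotype
#'   scale (default 1).
#' @param ld_decay Adjacent-marker haplotype correlation of the latent
#'   Markov chain in `[0, 1)` (default 0.5); 0 gives independent markers.
#' @param maf_floor Lower bound of the sampled allele-frequency spectrum
#'   (default 0.01).
#' @param ref_fraction Fraction of individuals in the reference set when
#'   `h2` is neither 0.45 nor 0.10 (those two use the fixed 2500/2500 and
#'   3750/1250 conventions at n = 5000).
#' @param seed Integer seed; every operation that consumes the config is
#'   deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 5000, n_markers = 10050, n_qtl = 50,
                       qtl_counts = c(17L, 16L, 17L),
                       architecture = c("mixture", "single_normal"),
                       h2 = 0.45, sigma_g2 = 1, ld_decay = 0.5,
                       maf_floor = 0.01, ref_fraction = 0.5, seed = NULL) {
  architecture <- match.arg(architecture)
  if (n_qtl > n_markers) stop("n_qtl must not exceed n_markers")
  if (architecture == "mixture" && sum(qtl_counts) != n_qtl) {
    stop("qtl_counts must sum to n_qtl for the mixture architecture")
  }
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (sigma_g2 <= 0) stop("sigma_g2 must be positive")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must lie in [0, 1)")
  if (maf_floor <= 0 || maf_floor >= 0.5) stop("maf_floor must lie in (0, 0.5)")
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
         qtl_counts = as.integer(qtl_counts), architecture = architecture,
         h2 = h2, sigma_g2 = sigma_g2, ld_decay = ld_decay,
         maf_floor = maf_floor, ref_fraction = ref_fraction,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

# Seed offsets keep the four stochastic stages independently reproducible
# while a full replicate remains a pure function of cfg$seed.
.sim_seed <- function(cfg, offset) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + offset)
}

#' Simulate genotype dosages
#'
#' Allele frequencies are drawn from a density proportional to `1/p` on
#' `[maf_floor, 1 - maf_floor]` (the shape of a neutral site-frequency
#' spectrum, truncated). Two haplotypes per individual are generated by
#' thresholding a latent Gaussian AR(1) process along the marker panel with
#' autocorrelation `ld_decay`, which induces linkage between nearby markers
#' while keeping each marker's frequency exact; the dosage is the haplotype
#' sum. This is a statistical surrogate for a forward population simulation:
#' it reproduces the frequency spectrum and short-range linkage, not
#' fine-scale coalescent LD.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .sim_seed(cfg, 0L)
  n <- cfg$n_individuals
  m <- cfg$n_markers
  a <- cfg$maf_floor
  p <- a * ((1 - a) / a)^stats::runif(m)   # inverse CDF of 1/p density
  q <- stats::qnorm(p)
  rho <- cfg$ld_decay
  s <- sqrt(1 - rho^2)
  dos <- matrix(0L, n, m)
  w1 <- stats::rnorm(n)
  w2 <- stats::rnorm(n)
  for (j in seq_len(m)) {
    if (j > 1L) {
      w1 <- rho * w1 + s * stats::rnorm(n)
      w2 <- rho * w2 + s * stats::rnorm(n)
    }
    dos[, j] <- (w1 < q[j]) + (w2 < q[j])
  }
  genotype_matrix(dos,
                  sample_ids = sprintf("ind_%05d", seq_len(n)),
                  marker_ids = sprintf("snp_%05d", seq_len(m)))
}

#' Assign QTL positions and effects
#'
#' Picks `n_qtl` markers uniformly at random from the panel (so the QTL are
#' genotyped) and draws their allele-substitution effects on the
#' standardized-genotype scale. Under the mixture architecture the
#' `qtl_counts` split the QTL over effect variances
#' `0.0006, 0.006, 0.06 x sigma_g2`; under the single-normal architecture
#' all effects come from `N(0, sigma_g2 / n_qtl)`.
#'
#' @param cfg A [sim_config()].
#' @param g A [genotype_matrix()] with at least `n_qtl` markers.
#' @return List with `qtl_idx` (marker indices), `qtl_effects`, and
#'   `qtl_class` (1-3 mixture class, or 0 for single-normal).
#' @export
assign_qtl_effects <- function(cfg, g) {
  stopifnot(inherits(cfg, "sim_config"), inherits(g, "genotype_matrix"))
  if (cfg$n_qtl > g$m) stop("more QTL requested than markers available")
  .sim_seed(cfg, 1L)
  idx <- sort(sample.int(g$m, cfg$n_qtl))
  if (cfg$n_qtl == 0L) {
    return(list(qtl_idx = integer(0), qtl_effects = numeric(0),
                qtl_class = integer(0)))
  }
  if (cfg$architecture == "mixture") {
    cls <- sample(rep.int(1:3, cfg$qtl_counts))
    vars <- c(0.0006, 0.006, 0.06) * cfg$sigma_g2
    eff <- stats::rnorm(cfg$n_qtl, 0, sqrt(vars[cls]))
  } else {
    cls <- integer(cfg$n_qtl)
    eff <- stats::rnorm(cfg$n_qtl, 0, sqrt(cfg$sigma_g2 / cfg$n_qtl))
  }
  list(qtl_idx = idx, qtl_effects = eff, qtl_class = cls)
}

#' Simulate phenotypes from true breeding values
#'
#' Residual variance is set from the realized variance of the breeding
#' values, `sigma_e2 = var(tbv) (1 - h2) / h2`, so the realized heritability
#' matches the configured one up to residual sampling noise.
#'
#' @param cfg A [sim_config()].
#' @param tbv Numeric vector of true breeding values.
#' @return List with `phenotypes` and `sigma_e2_used`.
#' @export
simulate_phenotypes <- function(cfg, tbv) {
  stopifnot(inherits(cfg, "sim_config"))
  .sim_seed(cfg, 2L)
  v <- stats::var(tbv)
  if (!is.finite(v) || v <= 0) {
    if (all(tbv == 0)) v <- 0 else stop("true breeding values have no variance")
  }
  sigma_e2 <- if (v == 0) 1 else v * (1 - cfg$h2) / cfg$h2
  list(phenotypes = tbv + stats::rnorm(length(tbv), 0, sqrt(sigma_e2)),
       sigma_e2_used = sigma_e2)
}

#' Split individuals into reference and validation sets
#'
#' At `h2 = 0.45` the split is half/half (2500/2500 at n = 5000); at
#' `h2 = 0.10` three quarters train (3750/1250 at n = 5000); at other
#' heritabilities `ref_fraction` decides. The split is random but
#' deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @param n Number of individuals to split.
#' @return List with integer index vectors `reference` and `validation`
#'   (disjoint, covering `1:n`).
#' @export
split_reference_validation <- function(cfg, n = cfg$n_individuals) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n < 2) stop("need at least two individuals to split")
  frac <- if (isTRUE(all.equal(cfg$h2, 0.45))) 0.5
          else if (isTRUE(all.equal(cfg$h2, 0.10))) 0.75
          else cfg$ref_fraction
  n_ref <- round(n * frac)
  if (n_ref < 1 || n_ref >= n) stop("requested split sizes exceed n")
  .sim_seed(cfg, 3L)
  ref <- sort(sample.int(n, n_ref))
  list(reference = ref, validation = setdiff(seq_len(n), ref))
}

#' Simulate one full replicate
#'
#' Runs the four stages (genotypes, QTL effects, phenotypes, split) and
#' computes the true breeding values `tbv = Z[, qtl] %*% effects` on the
#' replicate's own standardized scale.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_replicate`: list with `genotypes`,
#'   `qtl_idx`, `qtl_effects`, `qtl_class`, `tbv`, `phenotypes`,
#'   `sigma_e2_used`, `reference`, `validation` and `config`.
#' @examples
#' rep <- simulate_replicate(sim_config(n_individuals = 200, n_markers = 300,
#'                                      n_qtl = 10, qtl_counts = c(4, 3, 3),
#'                                      seed = 1))
#' length(rep$tbv)
#' @export
simulate_replicate <- function(cfg) {
  g <- simulate_genotypes(cfg)
  qtl <- assign_qtl_effects(cfg, g)
  if (length(qtl$qtl_idx)) {
    std <- standardize_genotypes(g)
    pos <- match(qtl$qtl_idx, std$kept_markers)
    if (anyNA(pos)) stop("a QTL marker is monomorphic in this replicate")
    tbv <- as.vector(std$Z[, pos, drop = FALSE] %*% qtl$qtl_effects)
  } else {
    tbv <- numeric(g$n)
  }
  ph <- simulate_phenotypes(cfg, tbv)
  sp <- split_reference_validation(cfg, g$n)
  structure(
    list(genotypes = g, qtl_idx = qtl$qtl_idx, qtl_effects = qtl$qtl_effects,
         qtl_class = qtl$qtl_class, tbv = tbv, phenotypes = ph$phenotypes,
         sigma_e2_used = ph$sigma_e2_used, reference = sp$reference,
         validation = sp$validation, config = cfg),
    class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("<sim_replicate> ", x$genotypes$n, " ind x ", x$genotypes$m,
      " markers, ", length(x$qtl_idx), " QTL, h2 = ", x$config$h2,
      " (", x$config$architecture, ")\n", sep = "")
  invisible(x)
}

#' Write a replicate to plain-text files
#'
#' Emits `dosages.tsv`, `phenotypes.tsv`, a `truth.tsv` with per-marker true
#' effects (zero off-QTL) plus reference/validation membership, and a
#' `config.json` sidecar.
#'
#' @param rep A [simulate_replicate()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_replicate <- function(rep, dir) {
  stopifnot(inherits(rep, "sim_replicate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_tsv(rep$genotypes, file.path(dir, "dosages.tsv"))
  write_phenotype_tsv(stats::setNames(rep$phenotypes, rep$genotypes$sample_ids),
                      file.path(dir, "phenotypes.tsv"))
  eff <- numeric(rep$genotypes$m)
  eff[rep$qtl_idx] <- rep$qtl_effects
  utils::write.table(
    data.frame(marker_id = rep$genotypes$marker_ids, true_effect = eff),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rep$genotypes$sample_ids,
               set = ifelse(seq_len(rep$genotypes$n) %in% rep$reference,
                            "reference", "validation"),
               tbv = rep$tbv),
    file.path(dir, "tbv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- rep$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
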