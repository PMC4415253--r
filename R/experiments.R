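#' Prediction accuracy
#'
#' Pearson correlation between predicted breeding values and the truth
#' (true breeding values in simulation; a phenotype surrogate on real data).
#'
#' @param gebv Predicted breeding values.
#' @param tbv Reference values of the same length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
accuracy <- function(gebv, tbv) {
  if (length(gebv) != length(tbv) || length(gebv) < 3) {
    stop("gebv and tbv must have equal length >= 3")
  }
  if (stats::var(gebv) == 0 || stats::var(tbv) == 0) {
    stop("zero variance in gebv or tbv")
  }
  stats::cor(gebv, tbv)
}

#' Prediction bias slope
#'
#' Ordinary least-squares regression coefficient of the truth on the
#' prediction; 1 indicates unbiased prediction (no systematic in/deflation
#' of predicted differences).
#'
#' @inheritParams accuracy
#' @return The slope `cov(tbv, gebv) / var(gebv)`.
#' @export
bias_slope <- function(gebv, tbv) {
  if (stats::var(gebv) == 0) stop("zero variance in gebv")
  stats::cov(tbv, gebv) / stats::var(gebv)
}

# Scenario name -> simulator configuration at the benchmark scale.
.scenario_config <- function(scenario, seed) {
  arch <- if (grepl("One", scenario)) "single_normal" else "mixture"
  h2 <- if (grepl("_10$", scenario)) 0.10 else 0.45
  sim_config(architecture = arch, h2 = h2, seed = seed)
}

# One master seed fans out to per-replicate seeds by a fixed affine rule so
# that every method sees identical data within a replicate and adding
# replicates never reshuffles earlier ones.
.replicate_seed <- function(seed, rep) {
  (as.integer(seed) * 1009L + 97L * as.integer(rep)) %% 2000000000L
}

#' Prepare one simulated replicate for estimation
#'
#' Simulates a replicate, standardizes reference and validation genotypes
#' with the reference-set allele frequencies, builds the reference GRM,
#' fits REML, and (optionally) the PEV summaries -- the shared inputs of
#' every estimator.
#'
#' @param cfg A [sim_config()].
#' @param pev Also compute the PEV summaries (default `TRUE`).
#' @return List with the replicate, `Z_ref`, `Z_val`, `y_ref`, `tbv_val`,
#'   `grm`, `vc`, `pev`, `prior_sigma_g2`.
#' @export
prepare_replicate <- function(cfg, pev = TRUE) {
  rep <- simulate_replicate(cfg)
  g_ref <- rep$genotypes[rep$reference]
  freqs_ref <- allele_frequencies(g_ref)
  Z_ref <- standardize_genotypes(g_ref, freqs = freqs_ref)
  Z_val <- standardize_genotypes(rep$genotypes[rep$validation],
                                 freqs = freqs_ref)
  y_ref <- rep$phenotypes[rep$reference]
  grm <- build_grm(Z_ref)
  vc <- reml_fit(grm, y_ref)
  pv <- if (pev) compute_pev(grm, vc, Z_ref) else NULL
  list(replicate = rep, Z_ref = Z_ref, Z_val = Z_val, y_ref = y_ref,
       tbv_val = rep$tbv[rep$validation], grm = grm, vc = vc, pev = pv)
}

# Align a fitted effect vector (on Z_ref's kept markers) with Z_val columns.
.val_gebv <- function(fit, Z_val) predict_gebv(Z_val, fit)

#' Run a benchmark scenario
#'
#' Simulates `n_replicates` datasets of the named architecture, fits the
#' requested methods on the reference half of each, and evaluates accuracy
#' (correlation of GEBV with TBV) and bias (slope of TBV on GEBV) on the
#' validation half. All methods within a replicate see identical data; the
#' whole table is a deterministic function of `(scenario, methods,
#' n_replicates, seed)`.
#'
#' @param scenario One of `"HD_Mix_45"`, `"HD_Mix_10"`, `"HD_One_45"`,
#'   `"HD_One_10"`: mixture or single-normal QTL effects at h2 0.45 / 0.10.
#' @param methods Character subset of `"embayesr"`, `"embayesr_nopev"`,
#'   `"embayesr_mean"`, `"bayesr"`, `"gblup"`, `"snpblup"`.
#' @param n_replicates Number of replicates (default 1).
#' @param seed Master seed.
#' @param gibbs A [gibbs_config()] for the `"bayesr"` method.
#' @param em A base [em_config()]; `use_pev` / `estimator` are overridden
#'   per method.
#' @param keep_fits Keep the fitted objects (default `FALSE`).
#' @param verbose Print per-method progress lines.
#' @param config_override Optional function `(cfg) -> cfg` applied to each
#'   replicate's [sim_config()] before simulation (e.g. to shrink the
#'   problem for demonstrations); the benchmark defaults are used as-is when
#'   `NULL`.
#' @return List of class `scenario_result` with `results` (tibble: one row
#'   per replicate x method with accuracy, bias, Pr, iterations), `summary`
#'   (mean and sd by method), and optionally `fits`.
#' @export
run_scenario <- function(scenario = c("HD_Mix_45", "HD_Mix_10", "HD_One_45",
                                      "HD_One_10"),
                         methods = c("embayesr", "gblup"),
                         n_replicates = 1, seed = 1,
                         gibbs = gibbs_config(), em = em_config(),
                         keep_fits = FALSE, verbose = FALSE,
                         config_override = NULL) {
  scenario <- match.arg(scenario)
  known <- c("embayesr", "embayesr_nopev", "embayesr_mean", "bayesr",
             "gblup", "snpblup")
  methods <- match.arg(methods, known, several.ok = TRUE)
  rows <- list()
  fits <- list()
  for (r in seq_len(n_replicates)) {
    rs <- .replicate_seed(seed, r)
    cfg <- .scenario_config(scenario, rs)
    if (!is.null(config_override)) cfg <- config_override(cfg)
    need_pev <- any(grepl("^embayesr", methods))
    prep <- tryCatch(prepare_replicate(cfg, pev = need_pev),
                     error = function(e) e)
    if (inherits(prep, "error")) {
      for (meth in methods) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scenario = scenario, replicate = r, method = meth,
          accuracy = NA_real_, bias_slope = NA_real_,
          n_validation = NA_integer_, pr1 = NA_real_, pr2 = NA_real_,
          pr3 = NA_real_, pr4 = NA_real_, iterations = NA_integer_,
          h2_reml = NA_real_, error = conditionMessage(prep))
      }
      next
    }
    prior <- mixture_prior(prep$vc$sigma_g2, profile = "10k")
    for (meth in methods) {
      row <- tryCatch({
        fit <- switch(
          meth,
          embayesr = embayesr(prep$y_ref, prep$Z_ref, prior,
                              modify_em(em, use_pev = TRUE, estimator = "mode"),
                              vc = prep$vc, pev = prep$pev),
          embayesr_nopev = embayesr(prep$y_ref, prep$Z_ref, prior,
                                    modify_em(em, use_pev = FALSE,
                                              estimator = "mode"),
                                    vc = prep$vc),
          embayesr_mean = embayesr(prep$y_ref, prep$Z_ref, prior,
                                   modify_em(em, use_pev = TRUE,
                                             estimator = "mean"),
                                   vc = prep$vc, pev = prep$pev),
          bayesr = bayesr_gibbs(prep$y_ref, prep$Z_ref, prior,
                                gibbs_config(gibbs$n_iter, gibbs$burn_in,
                                             gibbs$thin, seed = rs + 7L)),
          gblup = local({
            K_full <- build_grm(standardize_genotypes(
              prep$replicate$genotypes,
              freqs = allele_frequencies(
                prep$replicate$genotypes[prep$replicate$reference])))
            structure(list(
              gebv_val = gblup_predict(K_full, prep$y_ref, prep$vc,
                                       reference = prep$replicate$reference
              )$gebv[prep$replicate$validation]),
              class = "baseline_fit")
          }),
          snpblup = local({
            sb <- snp_blup(prep$Z_ref, prep$y_ref, prep$vc, K = prep$grm)
            structure(list(gebv_val = predict_gebv(prep$Z_val, sb$g_hat)),
                      class = "baseline_fit")
          }))
        gebv_val <- if (inherits(fit, "baseline_fit")) fit$gebv_val else
          .val_gebv(fit, prep$Z_val)
        if (keep_fits) fits[[paste(meth, r, sep = "_")]] <- fit
        pr <- if (inherits(fit, "embayesr_fit")) fit$Pr else
          if (inherits(fit, "bayesr_gibbs_fit")) fit$Pr_mean else rep(NA_real_, 4)
        out <- tibble::tibble(
          scenario = scenario, replicate = r, method = meth,
          accuracy = accuracy(gebv_val, prep$tbv_val),
          bias_slope = bias_slope(gebv_val, prep$tbv_val),
          n_validation = length(prep$tbv_val),
          pr1 = pr[1], pr2 = pr[2], pr3 = pr[3], pr4 = pr[4],
          iterations = if (inherits(fit, "embayesr_fit")) fit$iterations
                       else NA_integer_,
          h2_reml = prep$vc$h2, error = NA_character_)
        if (verbose) {
          message(sprintf("[%s rep %d] %-16s accuracy %.3f bias %.3f",
                          scenario, r, meth, out$accuracy, out$bias_slope))
        }
        out
      }, error = function(e) {
        tibble::tibble(scenario = scenario, replicate = r, method = meth,
                       accuracy = NA_real_, bias_slope = NA_real_,
                       n_validation = NA_integer_, pr1 = NA_real_,
                       pr2 = NA_real_, pr3 = NA_real_, pr4 = NA_real_,
                       iterations = NA_integer_, h2_reml = NA_real_,
                       error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  ok <- results[is.na(results$error), ]
  summary <- do.call(rbind, lapply(split(ok, ok$method), function(d) {
    tibble::tibble(scenario = scenario, method = d$method[1],
                   n_replicates = nrow(d),
                   mean_accuracy = mean(d$accuracy),
                   sd_accuracy = stats::sd(d$accuracy),
                   mean_bias = mean(d$bias_slope),
                   sd_bias = stats::sd(d$bias_slope))
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 fits = if (keep_fits) fits else NULL,
                 scenario = scenario, seed = seed),
            class = "scenario_result")
}

# Rebuild an em_config with some fields overridden.
modify_em <- function(em, use_pev = em$use_pev, estimator = em$estimator) {
  em_config(gamma = em$gamma, max_iter = em$max_iter, use_pev = use_pev,
            estimator = estimator, spike = em$spike,
            audit_every = em$audit_every)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scenario, ", seed ", x$seed, "\n", sep = "")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Sensitivity of the fit to the Dirichlet pseudo-counts
#'
#' Fits the EM on one shared replicate once per `alpha` setting, leaving
#' everything else identical, and reports the estimated mixing proportions
#' and validation accuracy per setting.
#'
#' @param alphas List of length-4 pseudo-count vectors.
#' @param scenario Scenario name as in [run_scenario()].
#' @param seed Master seed (replicate 1 of the scenario is used).
#' @param em An [em_config()].
#' @param prep Optional pre-built [prepare_replicate()] output to reuse.
#' @param config_override Optional function `(cfg) -> cfg`, as in
#'   [run_scenario()].
#' @return Tibble with one row per `alpha`: the four `Pr` estimates,
#'   accuracy and iteration count.
#' @export
prior_sensitivity <- function(alphas = list(c(1, 1, 1, 1), c(100, 1, 1, 1),
                                            c(1, 1, 100, 1), c(1, 1, 1, 100)),
                              scenario = "HD_Mix_45", seed = 1,
                              em = em_config(), prep = NULL,
                              config_override = NULL) {
  if (is.null(prep)) {
    cfg <- .scenario_config(scenario, .replicate_seed(seed, 1L))
    if (!is.null(config_override)) cfg <- config_override(cfg)
    prep <- prepare_replicate(cfg, pev = TRUE)
  }
  rows <- lapply(alphas, function(a) {
    prior <- mixture_prior(prep$vc$sigma_g2, profile = "10k", alpha = a)
    fit <- embayesr(prep$y_ref, prep$Z_ref, prior, em,
                    vc = prep$vc, pev = prep$pev)
    tibble::tibble(alpha = paste(a, collapse = ","),
                   pr1 = fit$Pr[1], pr2 = fit$Pr[2], pr3 = fit$Pr[3],
                   pr4 = fit$Pr[4],
                   accuracy = accuracy(.val_gebv(fit, prep$Z_val),
                                       prep$tbv_val),
                   iterations = fit$iterations)
  })
  do.call(rbind, rows)
}
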