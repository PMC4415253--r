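#' Four-component mixture prior on marker effects
#'
#' Marker effects are modelled as draws from a mixture of four normal
#' distributions `N(0, sigma_k2[k])` with `sigma_k2 = coeffs * sigma_g2`;
#' the first component has zero variance (a point mass at zero) and the
#' mixing proportions carry a Dirichlet prior with pseudo-counts `alpha`.
#' Two coefficient ladders are in common use: `"10k"` (0, 0.0006, 0.006,
#' 0.06) for panels where a small number of markers carries the signal, and
#' `"hd"` (0, 0.0001, 0.001, 0.01) for dense (>= 100 K) panels; in both
#' cases the ladder is chosen so that the variance summed over markers is
#' close to the genetic variance.
#'
#' @param sigma_g2 Total genetic variance that scales the ladder.
#' @param profile `"10k"` or `"hd"`, or ignore and give `coeffs`.
#' @param coeffs Length-4 increasing multipliers of `sigma_g2`; first must
#'   be 0.
#' @param alpha Length-4 positive Dirichlet pseudo-counts (default all 1).
#' @return An object of class `mixture_prior`: list with `coeffs`,
#'   `sigma_k2`, `alpha`, `sigma_g2`.
#' @examples
#' mixture_prior(sigma_g2 = 10, profile = "hd")$sigma_k2
#' @export
mixture_prior <- function(sigma_g2, profile = c("10k", "hd"), coeffs = NULL,
                          alpha = c(1, 1, 1, 1)) {
  if (is.null(coeffs)) {
    profile <- match.arg(profile)
    coeffs <- switch(profile,
                     "10k" = c(0, 0.0006, 0.006, 0.06),
                     "hd" = c(0, 0.0001, 0.001, 0.01))
  }
  if (length(coeffs) != 4 || coeffs[1] != 0 || any(diff(coeffs) <= 0)) {
    stop("coeffs must be 4 strictly increasing values starting at 0")
  }
  if (length(alpha) != 4 || any(alpha <= 0)) stop("alpha must be 4 positive values")
  if (sigma_g2 <= 0) stop("sigma_g2 must be positive")
  structure(list(coeffs = coeffs, sigma_k2 = coeffs * sigma_g2,
                 alpha = alpha, sigma_g2 = sigma_g2),
            class = "mixture_prior")
}

#' EM configuration
#'
#' @param gamma Convergence threshold on the relative squared change of the
#'   effect vector, `sum((g_q - g_{q-1})^2) / sum(g_q^2) < gamma`
#'   (default 1e-10, strict inequality).
#' @param max_iter Iteration backstop (default 50000).
#' @param use_pev Apply the prediction-error-variance correction
#'   (default `TRUE`; requires a `pev` argument to [embayesr()]).
#' @param estimator In-loop effect estimator: `"mode"` (conditional ridge
#'   mode, zero when the spike is the maximum-posterior component) or
#'   `"mean"` (full posterior mean across components).
#' @param spike Handling of the zero-variance component under the mode
#'   estimator: `"zero"` (default) sets the effect to exactly zero whenever
#'   the spike holds the largest posterior mass; `"ridge"` applies the
#'   ridge-mode formula unconditionally, in which case the spike exerts no
#'   shrinkage at all (kept for diagnosing that behaviour; it badly
#'   overfits when markers outnumber individuals).
#' @param update_sigma_e2 Re-estimate the error variance each sweep
#'   (default `TRUE`). With `FALSE` it stays at its initial (REML) value;
#'   see [embayesr()] for when that is the only well-defined choice.
#' @param audit_every Recompute the running residual from scratch every this
#'   many sweeps to bound numerical drift (default 1000; 0 disables).
#' @return An object of class `em_config`.
#' @export
em_config <- function(gamma = 1e-10, max_iter = 50000L, use_pev = TRUE,
                      estimator = c("mode", "mean"),
                      spike = c("zero", "ridge"), update_sigma_e2 = TRUE,
                      audit_every = 1000L) {
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(gamma = gamma, max_iter = as.integer(max_iter),
                 use_pev = isTRUE(use_pev), estimator = match.arg(estimator),
                 spike = match.arg(spike),
                 update_sigma_e2 = isTRUE(update_sigma_e2),
                 audit_every = as.integer(audit_every)),
            class = "em_config")
}

# ---- pure per-marker operations -------------------------------------------
# These scalar-statistic forms are the building blocks of the EM sweep; the
# compiled driver repeats them, and they are kept in R so each can be checked
# against brute-force oracles in isolation.

#' Marker statistic with the current marker's effect restored
#'
#' For marker `i`, the sweep needs `r_i = Z_i' y_dagger` where `y_dagger`
#' is the phenotype corrected for all other markers' effects and the mean.
#' With the running residual `e = y - Z g - 1 mu` this is
#' `r_i = Z_i' e + (Z_i' Z_i) g_i`, without materialising `y_dagger`.
#'
#' @param z_i Standardized genotype column.
#' @param residual Current running residual.
#' @param zz_i `Z_i' Z_i`.
#' @param g_i Current effect estimate of marker `i`.
#' @return The scalar `r_i`.
#' @export
residual_without_snp <- function(z_i, residual, zz_i, g_i) {
  sum(z_i * residual) + zz_i * g_i
}

#' Per-component marginal log-likelihood of a marker statistic
#'
#' Under component `k`, `r_i ~ N(0, v_ik)` with
#' `v_ik = zz_i^2 sigma_k2[k] + zz_i sigma_e2 + w_i`: prior effect variance
#' propagated through the design, residual noise, and the prediction-error
#' term `w_i = Z_i' PEV Z_i` that carries the estimation error of all other
#' markers (zero when the correction is off).
#'
#' @param r_i Marker statistic.
#' @param zz_i `Z_i' Z_i`.
#' @param w_i Per-marker PEV quadratic form (>= 0).
#' @param sigma_k2 Length-4 component variances (first 0).
#' @param sigma_e2 Error variance.
#' @return Length-4 vector of log-likelihoods.
#' @export
component_loglik <- function(r_i, zz_i, w_i, sigma_k2, sigma_e2) {
  v <- zz_i^2 * sigma_k2 + zz_i * sigma_e2 + w_i
  if (any(v <= 0)) stop("non-positive marginal variance; corrupt inputs")
  -0.5 * (log(v) + r_i^2 / v)
}

#' Posterior component membership probabilities for one marker
#'
#' `P_ik` proportional to `Pr_k exp(loglik_k)`, normalised with the
#' log-sum-exp trick.
#'
#' @param logliks Length-4 log-likelihood vector.
#' @param Pr Mixing proportions on the simplex.
#' @return Length-4 probability vector summing to one.
#' @export
component_posteriors <- function(logliks, Pr) {
  if (all(Pr == 0)) stop("all mixing proportions are zero")
  lp <- ifelse(Pr > 0, log(Pr), -Inf) + logliks
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Ridge-mode effect update (as-printed form)
#'
#' `g_i = r_i / (zz_i + P_i2 s_e2/s_22 + P_i3 s_e2/s_32 + P_i4 s_e2/s_42)`.
#' Note the zero-variance component contributes nothing to the denominator,
#' so at `P_i1 = 1` this is the least-squares value; the EM driver therefore
#' pairs it with a spike rule (see [em_config()]).
#'
#' @inheritParams component_loglik
#' @param P_i Length-4 posterior membership row.
#' @return Scalar effect estimate.
#' @export
snp_effect_mode <- function(r_i, zz_i, P_i, sigma_k2, sigma_e2) {
  den <- zz_i + sum(P_i[2:4] * sigma_e2 / sigma_k2[2:4])
  if (den <= 0) stop("non-positive denominator in mode update")
  r_i / den
}

#' Posterior-mean effect update
#'
#' `g_bar_i = sum_k P_ik r_i / (zz_i + sigma_e2 / sigma_k2[k])`, the spike
#' contributing zero. Never exceeds the least-squares value in magnitude.
#'
#' @inheritParams snp_effect_mode
#' @return Scalar effect estimate.
#' @export
snp_effect_mean <- function(r_i, zz_i, P_i, sigma_k2, sigma_e2) {
  r_i * sum(P_i[2:4] / (zz_i + sigma_e2 / sigma_k2[2:4]))
}

#' Mixing-proportion update
#'
#' `Pr_k` proportional to the soft component counts plus the Dirichlet
#' pseudo-counts: `(sum_i P_ik + alpha_k) / sum_k' (...)`. With all
#' `alpha = 1` this is the familiar "+1" estimator.
#'
#' @param P `m x 4` matrix of posterior membership rows.
#' @param alpha Length-4 pseudo-counts.
#' @return Length-4 simplex vector.
#' @export
update_mixing_proportions <- function(P, alpha = c(1, 1, 1, 1)) {
  s <- colSums(P) + alpha
  s / sum(s)
}

#' Error-variance update
#'
#' `sigma_e2 = (e'e + tr(PEV)) / n`; the trace term inflates the residual
#' sum of squares by the estimation error of the fitted breeding values and
#' is omitted when the PEV correction is off.
#'
#' @param residual Current residual `y - Z g - 1 mu`.
#' @param trace_pev `tr(PEV)` of the fitted breeding values.
#' @param use_pev Include the trace term.
#' @return Updated `sigma_e2`.
#' @export
update_error_variance <- function(residual, trace_pev, use_pev = TRUE) {
  (sum(residual^2) + if (use_pev) trace_pev else 0) / length(residual)
}

#' Mean update
#'
#' `mu = mean(y - Z g)`.
#'
#' @param y Phenotypes.
#' @param u_star Fitted breeding values `Z g`.
#' @return Updated mean.
#' @export
update_mean <- function(y, u_star) mean(y - u_star)

#' Convergence check on the effect vector
#'
#' Converged when `sum((g - g_prev)^2) / sum(g^2) < gamma` (strict). An
#' all-zero current vector leaves the ratio undefined: not converged, with
#' a `degenerate` flag.
#'
#' @param g_prev,g_curr Effect vectors from consecutive sweeps.
#' @param gamma Threshold.
#' @return List with `converged` and `degenerate` logicals and the `ratio`.
#' @export
convergence_check <- function(g_prev, g_curr, gamma) {
  den <- sum(g_curr^2)
  if (den <= 0) {
    return(list(converged = FALSE, degenerate = TRUE, ratio = NA_real_))
  }
  ratio <- sum((g_curr - g_prev)^2) / den
  list(converged = ratio < gamma, degenerate = FALSE, ratio = ratio)
}

#' Least-squares single-marker effect
#'
#' `g_ls = (Z_i'Z_i)^-1 Z_i'(y - 1 mu)`, the unshrunken reference point for
#' the mixture estimators.
#'
#' @param y Phenotypes.
#' @param Z A [standardize_genotypes()] result or matrix.
#' @param mu Mean to remove.
#' @param i Marker column index (omit for all markers).
#' @return Scalar (or vector) of least-squares effects.
#' @export
least_squares_effect <- function(y, Z, mu = mean(y), i = NULL) {
  M <- if (inherits(Z, "std_genotypes")) Z$Z else as.matrix(Z)
  if (!is.null(i)) M <- M[, i, drop = FALSE]
  as.vector(crossprod(M, y - mu)) / colSums(M^2)
}

# Choose the compact dosage layout when available; otherwise hand the dense
# double matrix to the compiled core.
.design_args <- function(Z, M) {
  if (inherits(Z, "std_genotypes") && !is.null(Z$dosages_raw)) {
    list(Z = matrix(numeric(0), 1, 0), Xraw = Z$dosages_raw,
         freqs = as.numeric(Z$freqs), scales = as.numeric(Z$scale),
         clean = Z$clean_cols)
  } else {
    list(Z = M, Xraw = matrix(raw(0), 0, 0), freqs = numeric(0),
         scales = numeric(0), clean = integer(0))
  }
}

# ---- EM driver -------------------------------------------------------------

#' Fit the EM mixture-model marker regression (emBayesR)
#'
#' Runs the full EM: initialise from the REML variance components
#' (`g = 0.01`, `Pr = (0.5, 0.487, 0.01, 0.003)`, `sigma_e2` from `vc`,
#' `mu = mean(y)`), then sweep markers in ascending order -- restoring each
#' marker's statistic `r_i`, updating its component posteriors and effect,
#' and the running residual -- and after each sweep update the mixing
#' proportions, error variance and mean, until the effect vector stabilises
#' at the `gamma` threshold. The prediction-error-variance summaries from
#' [compute_pev()] are computed once and held fixed, as is the `sigma_k2`
#' ladder.
#'
#' @param y Reference phenotypes (length n).
#' @param Z A [standardize_genotypes()] result (or bare matrix) for the
#'   reference individuals.
#' @param prior A [mixture_prior()].
#' @param config An [em_config()].
#' @param vc A [reml_fit()] result supplying the initial `sigma_e2` (and,
#'   via the prior, `sigma_g2`); any list with those elements works.
#' @param pev A [compute_pev()] result; required when `config$use_pev` and
#'   ignored by the ablated (`use_pev = FALSE`) variant, which treats the
#'   current estimates of all other markers as error-free. Note the ablation
#'   leaves the error variance without its trace correction, so at m > n its
#'   update can degenerate towards zero as the fit absorbs the residual;
#'   `em_config(update_sigma_e2 = FALSE)` holds it at the REML value instead.
#' @return An object of class `embayesr_fit`: list with `g_hat` (named
#'   effect vector), `P` (m x 4 membership matrix), `Pr`, `sigma_e2`, `mu`,
#'   `iterations`, `converged`, `degenerate`, `trajectory` (tibble with
#'   per-sweep `sigma_e2`, `pr1`, `ratio`), plus the inputs' metadata.
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(50 * 20), 50)
#' y <- Z[, 1] * 0.8 + rnorm(50)
#' fit <- embayesr(y, Z, mixture_prior(1),
#'                 em_config(use_pev = FALSE, max_iter = 500))
#' fit$Pr
#' @export
embayesr <- function(y, Z, prior, config = em_config(), vc = NULL, pev = NULL) {
  std <- inherits(Z, "std_genotypes")
  M <- if (std) Z$Z else as.matrix(Z)
  diag_zz <- if (std) Z$diag_zz else colSums(M^2)
  if (length(y) != nrow(M)) stop("length(y) must match nrow(Z)")
  stopifnot(inherits(prior, "mixture_prior"), inherits(config, "em_config"))
  if (config$use_pev && is.null(pev)) {
    stop("config$use_pev is TRUE but no pev summary was supplied")
  }
  # The ablation removes the PEV terms everywhere: the per-marker w_i from
  # the component likelihoods and the trace from the error-variance update.
  # Without the trace, sigma_e2 is not estimable when markers outnumber
  # individuals (the fit can absorb the whole residual and the update
  # degenerates towards zero); set update_sigma_e2 = FALSE to hold it at its
  # REML value instead when running the ablation diagnostically.
  use_trace <- config$use_pev
  sigma_e2_init <- if (!is.null(vc)) vc$sigma_e2 else {
    stats::var(y) * (1 - 0.5)   # fallback: half the phenotypic variance
  }
  if (prior$sigma_g2 <= 0) stop("prior sigma_g2 must be positive")
  w <- if (config$use_pev) as.numeric(pev$marker_terms) else numeric(ncol(M))
  if (config$use_pev && length(w) != ncol(M)) {
    stop("pev$marker_terms must have one entry per marker column")
  }
  tp <- if (use_trace) pev$trace_pev else 0

  a <- .design_args(Z, M)
  res <- em_fit_cpp(a$Z, a$Xraw, a$freqs, a$scales, a$clean,
                    as.numeric(y), diag_zz, prior$sigma_k2, prior$alpha,
                    w, tp, use_w = config$use_pev, use_trace = use_trace,
                    update_sigma_e2 = config$update_sigma_e2,
                    estimator = if (config$estimator == "mean") 1L else 0L,
                    spike_rule = if (config$spike == "ridge") 1L else 0L,
                    g_init = 0.01,
                    pr_init = c(0.5, 0.487, 0.01, 0.003),
                    sigma_e2_init = sigma_e2_init,
                    gamma = config$gamma, max_iter = config$max_iter,
                    audit_every = config$audit_every)
  if (!res$converged) {
    warning("EM did not converge within ", config$max_iter,
            " sweeps (last ratio ",
            format(utils::tail(res$trace_ratio, 1)), ")")
  }
  marker_ids <- if (std) Z$marker_ids else
    colnames(M) %||% paste0("snp_", seq_len(ncol(M)))
  structure(
    list(g_hat = stats::setNames(res$g, marker_ids), P = res$P, Pr = res$Pr,
         sigma_e2 = res$sigma_e2, mu = res$mu, residual = res$residual,
         iterations = res$iterations, converged = res$converged,
         degenerate = res$degenerate,
         max_residual_drift = res$max_residual_drift,
         trajectory = tibble::tibble(
           iteration = seq_along(res$trace_sigma_e2),
           sigma_e2 = res$trace_sigma_e2, pr1 = res$trace_pr1,
           ratio = res$trace_ratio),
         config = config, prior = prior,
         kept_markers = if (std) Z$kept_markers else seq_len(ncol(M)),
         m_input = if (std) Z$m_input else ncol(M),
         n = nrow(M)),
    class = "embayesr_fit")
}

#' @export
print.embayesr_fit <- function(x, ...) {
  cat(sprintf(paste0("<embayesr_fit> %d markers, n = %d; %s after %d sweeps\n",
                     "  Pr = (%s), sigma_e2 = %.4g, mu = %.4g\n"),
              length(x$g_hat), x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations,
              paste(sprintf("%.4f", x$Pr), collapse = ", "),
              x$sigma_e2, x$mu))
  invisible(x)
}

#' Predict breeding values from marker effects
#'
#' `GEBV = Z g_hat` on the target individuals' standardized genotypes
#' (standardize selection candidates with the training-set frequencies).
#' The population mean is excluded and reported separately by the fits.
#' Markers dropped as monomorphic during training carry effect zero.
#'
#' @param Z_target A [standardize_genotypes()] result or matrix for the
#'   target individuals, with the training markers in its columns.
#' @param g_hat Effect vector (e.g. `fit$g_hat`), or an `embayesr_fit` /
#'   `bayesr_gibbs_fit` object.
#' @return Numeric GEBV vector.
#' @export
predict_gebv <- function(Z_target, g_hat) {
  if (inherits(g_hat, "embayesr_fit")) g_hat <- g_hat$g_hat
  if (inherits(g_hat, "bayesr_gibbs_fit")) g_hat <- g_hat$g_mean
  M <- if (inherits(Z_target, "std_genotypes")) Z_target$Z else
    as.matrix(Z_target)
  if (!is.null(colnames(M)) && !is.null(names(g_hat))) {
    common <- intersect(colnames(M), names(g_hat))
    if (length(common) == 0) stop("no marker ids shared with the effect vector")
    M <- M[, common, drop = FALSE]
    g_hat <- g_hat[common]
  } else if (ncol(M) != length(g_hat)) {
    stop("Z_target columns do not match the effect vector")
  }
  as.vector(M %*% g_hat)
}

#' @importFrom tibble tibble
#' @export
tidy.embayesr_fit <- function(x, ...) {
  tibble::tibble(
    marker_id = names(x$g_hat), g_hat = unname(x$g_hat),
    p_null = x$P[, 1], p_small = x$P[, 2], p_medium = x$P[, 3],
    p_large = x$P[, 4], map_component = max.col(x$P))
}

#' @export
glance.embayesr_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations, converged = x$converged,
    sigma_e2 = x$sigma_e2, mu = x$mu,
    pr1 = x$Pr[1], pr2 = x$Pr[2], pr3 = x$Pr[3], pr4 = x$Pr[4],
    nonzero_effects = sum(x$g_hat != 0))
}

#' Broom-style tidiers
#'
#' `tidy()` returns one row per marker; `glance()` one row per fit.
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write a marker-effect table
#'
#' TSV with marker id, effect estimate, the four membership probabilities
#' and the maximum-posterior component.
#'
#' @param fit An `embayesr_fit` or `bayesr_gibbs_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(fit, path) {
  utils::write.table(as.data.frame(tidy(fit)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fit report (JSON)
#'
#' @param fit An `embayesr_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(
    list(iterations = fit$iterations, converged = fit$converged,
         Pr = fit$Pr, sigma_e2 = fit$sigma_e2, mu = fit$mu),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
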