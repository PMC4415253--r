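#' Genomic relationship matrix
#'
#' `K = Z Z' / m` on standardized genotypes, so that with many polymorphic
#' markers the diagonal averages one and the genetic variance parameter of
#' GBLUP is on the same scale as the mixture-prior variance ladder.
#'
#' @param Z A [standardize_genotypes()] result, or a bare numeric matrix of
#'   standardized genotypes.
#' @return An object of class `grm`: list with `K` (n x n symmetric matrix)
#'   and `n`, `m`.
#' @export
build_grm <- function(Z) {
  M <- if (inherits(Z, "std_genotypes")) Z$Z else as.matrix(Z)
  if (ncol(M) < 1) stop("need at least one marker")
  K <- tcrossprod(M) / ncol(M)
  structure(list(K = K, n = nrow(M), m = ncol(M)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", x$n, " x ", x$n, " from ", x$m,
      " markers; mean diagonal ", round(mean(diag(x$K)), 3), "\n", sep = "")
  invisible(x)
}

# One symmetric eigendecomposition of K serves REML, BLUP and PEV.
.grm_eigen <- function(K) {
  ev <- eigen(K, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  ev
}

#' REML variance components for the GBLUP model
#'
#' Fits `y = 1 mu + u + e`, `u ~ N(0, K sigma_g2)`, `e ~ N(0, I sigma_e2)`
#' by restricted maximum likelihood. After one eigendecomposition of `K`
#' the restricted log-likelihood is profiled in the total variance and
#' maximised over the heritability `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`
#' by one-dimensional search on `[1e-6, 1 - 1e-6]`.
#'
#' @param K A [build_grm()] result (or plain symmetric matrix).
#' @param y Numeric phenotype vector of length `n`.
#' @param eigen_K Optional precomputed `eigen(K)` to reuse.
#' @return An object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `h2`, `reml_loglik`, `flat_profile` (TRUE when the profile
#'   is numerically flat, e.g. `K = I` where only the total variance is
#'   identified), `boundary` (estimate at the search boundary), and the
#'   eigendecomposition for reuse.
#' @export
reml_fit <- function(K, y, eigen_K = NULL) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals for REML")
  if (nrow(Km) != n) stop("dim(K) must match length(y)")
  ev <- eigen_K %||% .grm_eigen(Km)
  d <- ev$values
  yt <- crossprod(ev$vectors, y)[, 1]
  xt <- crossprod(ev$vectors, rep(1, n))[, 1]

  # restricted log-likelihood at heritability h, total variance profiled out
  rll <- function(h) {
    ds <- h * d + (1 - h)
    wi <- 1 / ds
    xwx <- sum(xt^2 * wi)
    bhat <- sum(xt * yt * wi) / xwx
    r <- yt - xt * bhat
    sp2 <- sum(r^2 * wi) / (n - 1)
    -0.5 * (sum(log(ds)) + (n - 1) * log(sp2) + log(xwx) + (n - 1))
  }
  opt <- stats::optimize(rll, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum
  ds <- h2 * d + (1 - h2)
  wi <- 1 / ds
  xwx <- sum(xt^2 * wi)
  bhat <- sum(xt * yt * wi) / xwx
  sp2 <- sum((yt - xt * bhat)^2 * wi) / (n - 1)
  flat <- abs(opt$objective - rll(pmax(1e-6, h2 / 2))) < 1e-6 &&
    abs(opt$objective - rll(pmin(1 - 1e-6, (1 + h2) / 2))) < 1e-6
  boundary <- h2 < 1e-4 || h2 > 1 - 1e-4
  structure(
    list(sigma_g2 = h2 * sp2, sigma_e2 = (1 - h2) * sp2, h2 = h2,
         mu = bhat, reml_loglik = opt$objective,
         flat_profile = flat, boundary = boundary, eigen_K = ev),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (x$flat_profile) " (flat profile)" else ""))
  invisible(x)
}

#' GBLUP breeding-value prediction
#'
#' Standard mixed-model BLUP of `u` for all individuals from reference
#' phenotypes: `u_hat = sigma_g2 K[, ref] (sigma_g2 K[ref, ref] +
#' sigma_e2 I)^-1 (y_ref - 1 mu_hat)` with the mean estimated by GLS.
#'
#' @param K_full A [build_grm()] over reference plus validation individuals.
#' @param y_ref Phenotypes of the reference individuals.
#' @param reference Integer indices of the reference individuals within
#'   `K_full` (defaults to the first `length(y_ref)` rows).
#' @param vc A [reml_fit()] result (or list with `sigma_g2`, `sigma_e2`).
#' @return List with `gebv` (length n vector, reference and validation),
#'   `mu` (GLS mean estimate).
#' @export
gblup_predict <- function(K_full, y_ref, vc, reference = seq_along(y_ref)) {
  Km <- if (inherits(K_full, "grm")) K_full$K else as.matrix(K_full)
  nr <- length(y_ref)
  if (length(reference) != nr) stop("reference must index y_ref")
  sg <- vc$sigma_g2
  se <- vc$sigma_e2
  if (sg <= 0) return(list(gebv = numeric(nrow(Km)), mu = mean(y_ref)))
  V <- sg * Km[reference, reference, drop = FALSE]
  diag(V) <- diag(V) + se
  Vi <- tryCatch(solve(V), error = function(e) {
    diag(V) <- diag(V) + 1e-6 * mean(diag(V))
    solve(V)
  })
  one <- rep(1, nr)
  mu <- sum(Vi %*% y_ref) / sum(Vi)
  a <- Vi %*% (y_ref - mu)
  gebv <- as.vector(sg * Km[, reference, drop = FALSE] %*% a)
  list(gebv = gebv, mu = mu)
}

#' Prediction-error variance of the GBLUP breeding values
#'
#' The prediction error covariance of `u_hat` under the GBLUP model with the
#' fixed mean absorbed by GLS projection:
#' `PEV = sigma_g2 K - sigma_g2 K P K sigma_g2` with
#' `P = V^-1 - V^-1 1 (1' V^-1 1)^-1 1' V^-1`, `V = sigma_g2 K + sigma_e2 I`.
#' Returns the two summaries the EM correction consumes: the trace
#' `tr(PEV)` and the per-marker quadratic forms `w_i = Z_i' PEV Z_i`.
#' Everything is computed through one eigendecomposition of `K`; the full
#' matrix is materialised only on request.
#'
#' @param K A [build_grm()] over the reference individuals.
#' @param vc A [reml_fit()] result.
#' @param Z A [standardize_genotypes()] result for the same individuals (or
#'   a bare matrix), used for the per-marker terms; may be `NULL` to skip.
#' @param return_matrix If `TRUE`, also return the n x n PEV matrix.
#' @return An object of class `pev_summary`: list with `trace_pev`,
#'   `marker_terms` (named vector `w_i >= 0`, `NULL` when `Z` is), and
#'   optionally `PEV`.
#' @export
compute_pev <- function(K, vc, Z = NULL, return_matrix = FALSE) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  n <- nrow(Km)
  sg <- vc$sigma_g2
  se <- vc$sigma_e2
  M <- if (inherits(Z, "std_genotypes")) Z$Z else Z
  if (!is.null(M) && nrow(M) != n) stop("Z and K must cover the same individuals")
  if (sg <= 0) {
    out <- list(trace_pev = 0,
                marker_terms = if (is.null(M)) NULL else
                  stats::setNames(numeric(ncol(M)), colnames(M)))
    return(structure(out, class = "pev_summary"))
  }
  ev <- vc$eigen_K %||% .grm_eigen(Km)
  d <- ev$values
  v <- sg * d + se
  s0 <- sg * d * se / v                       # spectrum of the no-mean PEV
  xt <- crossprod(ev$vectors, rep(1, n))[, 1]
  sxx <- sum(xt^2 / v)                        # 1' V^-1 1
  cvec <- sg * d * xt / v                     # coords of sigma_g2 K V^-1 1
  trace_pev <- sum(s0) + sum(cvec^2) / sxx
  marker_terms <- NULL
  if (!is.null(M)) {
    A <- crossprod(ev$vectors, M)             # U'Z, n x m
    marker_terms <- colSums(A^2 * s0) + as.vector(crossprod(A, cvec))^2 / sxx
    if (any(marker_terms < -1e-6)) stop("PEV quadratic form went negative")
    marker_terms[marker_terms < 0] <- 0
    names(marker_terms) <- colnames(M)
  }
  out <- list(trace_pev = trace_pev, marker_terms = marker_terms)
  if (return_matrix) {
    P0 <- ev$vectors %*% (s0 * t(ev$vectors))
    cfull <- ev$vectors %*% cvec
    out$PEV <- P0 + tcrossprod(cfull) / sxx
  }
  structure(out, class = "pev_summary")
}

#' @export
print.pev_summary <- function(x, ...) {
  cat(sprintf("<pev_summary> tr(PEV) = %.4g%s\n", x$trace_pev,
              if (is.null(x$marker_terms)) "" else
                sprintf(", %d marker terms (mean %.4g)",
                        length(x$marker_terms), mean(x$marker_terms))))
  invisible(x)
}

#' SNP-BLUP (ridge) marker effects via the GBLUP identity
#'
#' Ridge-regression effects with penalty `lambda = m sigma_e2 / sigma_g2`
#' computed through the equivalent animal model:
#' `g_hat = (sigma_g2 / m) Z' (sigma_g2 K + sigma_e2 I)^-1 (y - 1 mu_hat)`,
#' so that `Z g_hat` equals the GBLUP breeding values exactly.
#'
#' @param Z A [standardize_genotypes()] result for the reference set.
#' @param y Reference phenotypes.
#' @param vc A [reml_fit()] result.
#' @param K Optional [build_grm()] to reuse.
#' @return List with `g_hat` (marker effects) and `mu`.
#' @export
snp_blup <- function(Z, y, vc, K = NULL) {
  M <- if (inherits(Z, "std_genotypes")) Z$Z else as.matrix(Z)
  Km <- if (is.null(K)) tcrossprod(M) / ncol(M) else
    (if (inherits(K, "grm")) K$K else K)
  V <- vc$sigma_g2 * Km
  diag(V) <- diag(V) + vc$sigma_e2
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  a <- Vi %*% (y - mu)
  g_hat <- as.vector((vc$sigma_g2 / ncol(M)) * crossprod(M, a))
  list(g_hat = stats::setNames(g_hat, colnames(M)), mu = mu)
}
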