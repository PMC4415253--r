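# Unit checks of the per-marker operations, including brute-force oracles
# for the component posteriors and the posterior-mean update.

test_that("the marker statistic matches the explicit corrected phenotype", {
  set.seed(20)
  n <- 20; m <- 50
  Z <- matrix(rnorm(n * m), n, m)
  g <- rnorm(m, sd = 0.1)
  mu <- 0.3
  y <- as.vector(Z %*% g) + mu + rnorm(n)
  e <- y - as.vector(Z %*% g) - mu
  for (i in sample(m, 10)) {
    y_dagger <- y - as.vector(Z[, -i] %*% g[-i]) - mu
    expect_equal(residual_without_snp(Z[, i], e, sum(Z[, i]^2), g[i]),
                 sum(Z[, i] * y_dagger), tolerance = 1e-10)
  }
  # with a zero effect it is just the residual projection
  expect_equal(residual_without_snp(Z[, 1], e, sum(Z[, 1]^2), 0),
               sum(Z[, 1] * e))
})

test_that("component log-likelihood has the stated marginal variances", {
  # null component: v = zz * sigma_e2 (+ w)
  ll <- component_loglik(1.3, zz_i = 10, w_i = 0,
                         sigma_k2 = c(0, 1e-3, 1e-2, 0.06), sigma_e2 = 2)
  expect_equal(ll[1], -0.5 * (log(20) + 1.3^2 / 20))
  # arithmetic spot check of the largest component
  ll2 <- component_loglik(0, zz_i = 2500, w_i = 0,
                          sigma_k2 = c(0, 6e-4, 6e-3, 0.06), sigma_e2 = 1)
  expect_equal(ll2[4], -0.5 * log(2500^2 * 0.06 + 2500))
  expect_error(component_loglik(1, 0, 0, c(0, 1, 2, 3), 0), "non-positive")
})

test_that("component posteriors normalise and respect degenerate priors", {
  Pr <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(component_posteriors(rep(-1.7, 4), Pr), Pr)
  expect_equal(component_posteriors(c(-5, -1, -2, -9), c(1, 0, 0, 0)),
               c(1, 0, 0, 0))
  expect_error(component_posteriors(rep(0, 4), rep(0, 4)), "zero")
  # an extreme statistic pushes all mass to the widest component
  sk <- c(0, 6e-4, 6e-3, 0.06)
  v4 <- 100^2 * 0.06 + 100
  r <- 1e3 * sqrt(v4)
  P <- component_posteriors(component_loglik(r, 100, 0, sk, 1),
                            c(0.97, 0.01, 0.01, 0.01))
  expect_gt(P[4], 1 - 1e-12)
})

test_that("single-marker posteriors match numeric quadrature", {
  # oracle: integrate the exact single-marker posterior over the effect for
  # each component; compare memberships and the posterior mean
  sk <- c(0, 6e-4, 6e-3, 0.06)
  Pr <- c(0.5, 0.487, 0.01, 0.003)
  set.seed(33)
  for (rep in 1:50) {
    n <- 10
    z <- rnorm(n)
    se2 <- runif(1, 0.5, 2)
    g_true <- rnorm(1, 0, 0.3)
    yd <- z * g_true + rnorm(n, 0, sqrt(se2))
    zz <- sum(z^2)
    r <- sum(z * yd)
    # component marginal likelihoods by 1-D quadrature (k = 1 in closed form)
    lik_data <- function(g) exp(-0.5 * sum((yd - z * g)^2) / se2)
    marg <- vapply(2:4, function(k) {
      integrate(function(gs) {
        vapply(gs, function(g) lik_data(g) * dnorm(g, 0, sqrt(sk[k])),
               numeric(1))
      }, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
    marg <- c(lik_data(0), marg)
    P_oracle <- Pr * marg / sum(Pr * marg)
    P_pkg <- component_posteriors(component_loglik(r, zz, 0, sk, se2), Pr)
    expect_equal(P_pkg, P_oracle, tolerance = 1e-6)
    # posterior mean by quadrature vs the closed-form update
    num <- sum(vapply(2:4, function(k) {
      integrate(function(gs) {
        vapply(gs, function(g) g * lik_data(g) * dnorm(g, 0, sqrt(sk[k])),
               numeric(1))
      }, -Inf, Inf, rel.tol = 1e-10)$value * Pr[k]
    }, numeric(1)))
    mean_oracle <- num / sum(Pr * marg)
    expect_equal(snp_effect_mean(r, zz, P_pkg, sk, se2), mean_oracle,
                 tolerance = 1e-6)
  }
})

test_that("the printed ridge-mode update has its stated limits", {
  sk <- c(0, 1e-3, 1e-2, 0.1)
  # spike-only membership leaves least squares untouched (the printed form)
  expect_equal(snp_effect_mode(2, 10, c(1, 0, 0, 0), sk, 1), 0.2)
  expect_equal(snp_effect_mode(0, 10, c(0.2, 0.3, 0.3, 0.2), sk, 1), 0)
  # single wide component with negligible shrinkage ratio
  expect_equal(snp_effect_mode(2, 10, c(0, 0, 0, 1), sk, 1e-9), 0.2,
               tolerance = 1e-8)
  expect_equal(least_squares_effect(c(1, 2, 3), matrix(c(1, 0, 0), 3), mu = 0),
               1)
})

test_that("the posterior-mean update never exceeds least squares", {
  sk <- c(0, 1e-3, 1e-2, 0.1)
  expect_equal(snp_effect_mean(2, 10, c(1, 0, 0, 0), sk, 1), 0)
  expect_equal(snp_effect_mean(2, 10, c(0, 0, 0, 1), sk, 1),
               2 / (10 + 1 / 0.1))
  set.seed(9)
  for (i in 1:100) {
    P <- as.vector(rmultinom(1, 20, runif(4))) / 20
    r <- rnorm(1, sd = 5)
    zz <- runif(1, 1, 50)
    se2 <- runif(1, 0.1, 3)
    expect_lte(abs(snp_effect_mean(r, zz, P, sk, se2)), abs(r / zz) + 1e-12)
  }
})

test_that("mixing-proportion updates add pseudo-counts to soft counts", {
  P <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(update_mixing_proportions(P), c(2, 2, 1, 1) / 6)
  P2 <- matrix(rep(c(1, 0, 0, 0), each = 100), 100, 4)
  expect_equal(update_mixing_proportions(P2), c(101, 1, 1, 1) / 104)
  # a big pseudo-count drags the estimate towards its component
  pr_flat <- update_mixing_proportions(P2, alpha = c(1, 1, 1, 1))
  pr_up <- update_mixing_proportions(P2, alpha = c(100, 1, 1, 1))
  expect_gt(pr_up[1], pr_flat[1])
  expect_simplex(pr_up)
})

test_that("error-variance and mean updates are the stated closed forms", {
  res <- c(1, 2, 1, 2)
  expect_equal(update_error_variance(res, trace_pev = 2), (10 + 2) / 4)
  expect_equal(update_error_variance(res, trace_pev = 2, use_pev = FALSE),
               update_error_variance(res, trace_pev = 0))
  expect_equal(update_error_variance(numeric(3), 0), 0)
  y <- rnorm(10)
  u <- rnorm(10)
  expect_equal(update_mean(y, u), mean(y - u))
  expect_equal(update_mean(y + 5, u), update_mean(y, u) + 5)
})

test_that("convergence uses a strict threshold and flags the zero vector", {
  g <- c(0.1, -0.2)
  expect_true(convergence_check(g, g, 1e-10)$converged)
  # ratio exactly gamma is not converged
  gp <- c(1, 0)
  gc <- c(1 + sqrt(1e-10 * 1), 0)
  ratio <- sum((gc - gp)^2) / sum(gc^2)
  expect_false(convergence_check(gp, gc, ratio)$converged)
  z <- convergence_check(g, c(0, 0), 1e-10)
  expect_false(z$converged)
  expect_true(z$degenerate)
})
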