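#' Convergence trajectory plot
#'
#' Error variance, null-component mixing proportion and the convergence
#' ratio per EM sweep, on free y scales.
#'
#' @param fit An [embayesr()] result.
#' @return A ggplot object.
#' @export
plot_convergence <- function(fit) {
  stopifnot(inherits(fit, "embayesr_fit"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_convergence() needs the ggplot2 package")
  }
  tr <- fit$trajectory
  d <- rbind(
    data.frame(iteration = tr$iteration, value = tr$sigma_e2,
               quantity = "sigma_e2"),
    data.frame(iteration = tr$iteration, value = tr$pr1, quantity = "Pr[1]"),
    data.frame(iteration = tr$iteration, value = log10(tr$ratio),
               quantity = "log10 convergence ratio"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "EM sweep", y = NULL)
}

#' Shrinkage plot: estimates against least squares
#'
#' @param fit An `embayesr_fit` or `bayesr_gibbs_fit`.
#' @param y,Z The phenotypes and standardized genotypes the fit used.
#' @return A ggplot object.
#' @export
plot_shrinkage <- function(fit, y, Z) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_shrinkage() needs the ggplot2 package")
  }
  ls <- least_squares_effect(y, Z)
  g <- if (inherits(fit, "bayesr_gibbs_fit")) fit$g_mean else fit$g_hat
  d <- data.frame(least_squares = ls, estimate = unname(g))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$least_squares, y = .data$estimate)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "least-squares estimate", y = "mixture-model estimate")
}

#' @export
autoplot.embayesr_fit <- function(object, ...) plot_convergence(object)

#' Autoplot methods
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @name autoplot
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' @rdname autoplot
#' @export
autoplot.scenario_result <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot needs the ggplot2 package")
  }
  d <- as.data.frame(object$results[is.na(object$results$error), ])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "accuracy (cor(GEBV, TBV))",
                  title = object$scenario)
}
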