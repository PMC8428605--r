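#' @export
print.twomix <- function(x, ...) {
  cat("Two-mixture empirical Bayes fit\n")
  cat("  units:", x$stats$m,
      if (!is.null(x$subsample_idx))
        paste0("(fitted on ", length(x$subsample_idx), ")"), "\n")
  cat("  effect grid: 2K+1 =", length(x$g), "points, mode",
      x$egrid$mode_value, "; variance grid: L =", x$vgrid$L, "\n")
  cat("  log-likelihood:", format(x$loglik), "(",
      if (x$converged) "converged" else "not converged",
      "in", x$n_outer, "outer cycles )\n")
  cat("  estimated null proportion pi0:", signif(x$pi0, 4), "\n")
  invisible(x)
}

#' Summary of a two-mixture fit
#'
#' @param object a `"twomix"` object.
#' @param alpha discovery threshold used in the summary counts. Default 0.1.
#' @param ... unused.
#' @return An object of class `"summary.twomix"`.
#' @export
summary.twomix <- function(object, alpha = 0.1, ...) {
  cons <- verify_constraints(object)
  post <- object$posterior
  out <- list(
    m = object$stats$m, df = object$stats$df,
    K = object$egrid$K, L = object$vgrid$L,
    loglik = object$loglik, converged = object$converged,
    n_outer = object$n_outer,
    pi0 = object$pi0,
    constraints = cons,
    alpha = alpha,
    n_lfdr = discovery_list(post, alpha, "lfdr")$n,
    n_lfsr = discovery_list(post, alpha, "lfsr")$n,
    lfdr_quartiles = stats::quantile(post$lfdr, c(.25, .5, .75)),
    g_support = range(object$egrid$values),
    h_support = range(object$vgrid$values)
  )
  class(out) <- "summary.twomix"
  out
}

#' @export
print.summary.twomix <- function(x, ...) {
  cat("Two-mixture empirical Bayes fit:", x$m, "units, df =", x$df, "\n")
  cat("  grids: 2K+1 =", 2 * x$K + 1, "effects on [",
      signif(x$g_support[1], 4), ",", signif(x$g_support[2], 4),
      "]; L =", x$L, "variances on [",
      signif(x$h_support[1], 4), ",", signif(x$h_support[2], 4), "]\n")
  cat("  log-likelihood", format(x$loglik),
      if (x$converged) "(converged)" else "(NOT converged)",
      "after", x$n_outer, "outer cycles\n")
  cat("  constraints ok:", x$constraints$ok,
      "( simplex", format(x$constraints$max_simplex_violation, digits = 2),
      "/ ordering", format(x$constraints$max_order_violation, digits = 2), ")\n")
  cat("  pi0-hat:", signif(x$pi0, 4), "\n")
  cat("  lfdr quartiles:", paste(signif(x$lfdr_quartiles, 3), collapse = " / "), "\n")
  cat("  discoveries at", x$alpha, ": lfdr", x$n_lfdr, ", lfsr", x$n_lfsr, "\n")
  invisible(x)
}

#' Extract the estimated mixing distributions
#'
#' @param object a `"twomix"` object.
#' @param ... unused.
#' @return list with `g` (named by effect grid values) and `h` (named by
#'   variance grid values).
#' @export
coef.twomix <- function(object, ...) {
  list(g = stats::setNames(object$g, format(object$egrid$values, digits = 6)),
       h = stats::setNames(object$h, format(object$vgrid$values, digits = 6)))
}

#' Log-likelihood of a two-mixture fit
#'
#' @param object a `"twomix"` object.
#' @param ... unused.
#' @return `"logLik"` object; the nominal parameter count is
#'   `(2K + 1 - 1) + (L - 1)` (two simplices).
#' @export
logLik.twomix <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- (length(object$g) - 1L) + (length(object$h) - 1L)
  attr(val, "nobs") <- if (is.null(object$subsample_idx)) object$stats$m
                       else length(object$subsample_idx)
  class(val) <- "logLik"
  val
}

#' Posterior mean effects
#'
#' @param object a `"twomix"` object.
#' @param ... unused.
#' @return numeric vector of posterior expected effects per unit.
#' @export
fitted.twomix <- function(object, ...) {
  as.vector(object$posterior$P %*% object$egrid$values)
}

#' Effect-scale residuals
#'
#' The difference between each observed effect estimate and its posterior
#' mean effect (the model's shrunken estimate).
#'
#' @param object a `"twomix"` object.
#' @param ... unused.
#' @return numeric vector.
#' @export
residuals.twomix <- function(object, ...) {
  object$stats$x - fitted(object)
}

#' Posterior inference for new units under a fitted model
#'
#' Evaluates the fitted mixing distributions on new summary statistics
#' (sharing the model's degrees-of-freedom convention) and returns their
#' posterior table, lfdr and lfsr.
#'
#' @param object a `"twomix"` object.
#' @param newdata a [summary_stats()] object, or a list/data.frame with
#'   components `x` and `s2` (and optionally `unit_ids`); `df` defaults to
#'   the fitted one. `NULL` returns the stored posterior.
#' @param ... unused.
#' @return a `"twomix_posterior"` object.
#' @export
predict.twomix <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posterior)
  if (!inherits(newdata, "summary_stats"))
    newdata <- summary_stats(x = newdata$x, s2 = newdata$s2,
                             df = newdata$df %||% object$stats$df,
                             unit_ids = newdata$unit_ids)
  posterior_effects(object, newdata)
}

#' Simulate summary statistics from a fitted two-mixture model
#'
#' Draws latent effects from the estimated `g`, latent variances from the
#' estimated `h`, then observed pairs from the sampling model
#' `x ~ N(theta, sigma2)`, `s2 ~ (sigma2 / df) * chisq(df)`.
#'
#' @param object a `"twomix"` object.
#' @param nsim number of replicate datasets. Default 1.
#' @param seed optional integer seed; the global RNG stream is restored.
#' @param m units per replicate; defaults to the fitted number of units.
#' @param ... unused.
#' @return list of `nsim` data frames with columns `theta`, `sigma2`, `x`,
#'   `s2`.
#' @export
simulate.twomix <- function(object, nsim = 1, seed = NULL,
                            m = object$stats$m, ...) {
  df <- object$stats$df
  a <- object$egrid$values
  b <- object$vgrid$values
  with_seed(seed, lapply(seq_len(nsim), function(j) {
    theta <- sample(a, m, replace = TRUE, prob = object$g)
    sigma2 <- sample(b, m, replace = TRUE, prob = object$h)
    data.frame(theta = theta, sigma2 = sigma2,
               x = stats::rnorm(m, theta, sqrt(sigma2)),
               s2 = sigma2 * stats::rchisq(m, df) / df)
  }))
}

#' Plot the estimated mixing distributions
#'
#' Draws the cumulative distribution functions of the estimated effect
#' mixing distribution `g` (left) and variance mixing distribution `h`
#' (right), in the style customary for fitted mixing distributions.
#'
#' @param x a `"twomix"` object.
#' @param which `"both"` (default), `"g"` or `"h"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.twomix <- function(x, which = c("both", "g", "h"), ...) {
  which <- match.arg(which)
  draw_cdf <- function(sup, mass, main, xlab) {
    graphics::plot(sup, cumsum(mass), type = "s", ylim = c(0, 1),
                   xlab = xlab, ylab = "CDF", main = main, ...)
    graphics::points(sup, cumsum(mass), pch = 16, cex = 0.5)
  }
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "g"))
    draw_cdf(x$egrid$values, x$g, "Effect mixing distribution g", "effect")
  if (which %in% c("both", "h"))
    draw_cdf(x$vgrid$values, x$h, "Variance mixing distribution h",
             "squared standard error")
  invisible(x)
}
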