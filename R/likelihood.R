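#' Log density of the scaled chi-square model for a squared standard error
#'
#' Under normal sampling, a squared standard error with `df` degrees of
#' freedom and true variance `b` satisfies `df * s2 / b ~ chisq(df)`, so the
#' density of `s2` is `(df / b) * dchisq(df * s2 / b, df)`. Returned on the
#' log scale; `-Inf` is a valid value where the density vanishes.
#'
#' @param s2 observed squared standard error(s), strictly positive.
#' @param b true variance grid point(s), strictly positive.
#' @param df degrees of freedom, `>= 1`.
#' @return log-density, vectorized over `s2` and `b`.
#' @export
#' @examples
#' scaled_chisq_logpdf(1, 1, df = 2)  # log(exp(-1)) = -1
scaled_chisq_logpdf <- function(s2, b, df) {
  if (any(!is.finite(s2)) || any(s2 <= 0)) stop("'s2' must be finite and > 0")
  if (any(!is.finite(b)) || any(b <= 0)) stop("'b' must be finite and > 0")
  if (length(df) != 1L || !is.finite(df) || df < 1) stop("'df' must be a scalar >= 1")
  log(df / b) + stats::dchisq(df * s2 / b, df = df, log = TRUE)
}

#' Log density of the Gaussian component for an effect estimate
#'
#' The effect estimate is modelled as Gaussian, centred at a grid effect `a`
#' with variance equal to the grid variance `b`:
#' `log dnorm(x, mean = a, sd = sqrt(b))`.
#'
#' @param x observed effect estimate(s).
#' @param a effect grid point(s).
#' @param b variance grid point(s), strictly positive.
#' @return log-density, vectorized.
#' @export
#' @examples
#' normal_component_logpdf(0, 0, 1)  # log(0.39894...)
normal_component_logpdf <- function(x, a, b) {
  if (any(!is.finite(b)) || any(b <= 0)) stop("'b' must be finite and > 0")
  stats::dnorm(x, mean = a, sd = sqrt(b), log = TRUE)
}

#' Per-unit component log-likelihood table
#'
#' For every unit i and grid pair (a_k, b_l), the log joint density of the
#' observed pair (x_i, s2_i) given theta_i = a_k and sigma2_i = b_l:
#' the Gaussian factor for x_i plus the scaled chi-square factor for s2_i.
#' The chi-square factor does not depend on k and is computed once per
#' (i, l) and cached.
#'
#' @param stats a [summary_stats()] object.
#' @param egrid an [effect_grid()].
#' @param vgrid a [variance_grid()].
#' @return An object of class `"component_loglik"`: list with `entries`
#'   (an `m x (2K+1) x L` array), `chisq_part` (`m x L` matrix), and the
#'   grids and `df` used.
#' @export
component_loglik <- function(stats, egrid, vgrid) {
  stopifnot(inherits(stats, "summary_stats"),
            inherits(egrid, "effect_grid"),
            inherits(vgrid, "variance_grid"))
  m <- stats$m
  a <- egrid$values
  b <- vgrid$values
  nk <- length(a); L <- length(b)
  chisq_part <- matrix(0, m, L)
  for (l in seq_len(L))
    chisq_part[, l] <- scaled_chisq_logpdf(stats$s2, b[l], stats$df)
  entries <- array(0, dim = c(m, nk, L))
  for (l in seq_len(L)) {
    sdl <- sqrt(b[l])
    for (k in seq_len(nk))
      entries[, k, l] <- stats::dnorm(stats$x, a[k], sdl, log = TRUE) + chisq_part[, l]
  }
  structure(
    list(entries = entries, chisq_part = chisq_part,
         egrid = egrid, vgrid = vgrid, df = stats$df, m = m),
    class = "component_loglik"
  )
}

#' Mixture log-likelihood and its gradient
#'
#' The objective of the constrained MLE: for mixing weights `g` over the
#' effect grid and `h` over the variance grid,
#' `l(g, h) = sum_i log sum_k sum_l g_k h_l p_i(k, l)`,
#' where `p_i(k, l)` are the component densities. Evaluated in log space with
#' per-unit log-sum-exp stabilization. Gradients are the exact partial
#' derivatives `d l / d g_k = sum_i A_ik / den_i` (with
#' `A_ik = sum_l h_l p_i(k,l)`) and symmetrically for `h`.
#'
#' @param g probability vector over the effect grid (length `2K + 1`).
#'   Nonnegative; sums are not enforced, so the objective can be probed
#'   slightly off the simplex (e.g. for finite-difference gradient checks).
#' @param h probability vector over the variance grid (length `L`),
#'   nonnegative.
#' @param comp a [component_loglik()] table.
#' @return list with `loglik` (scalar; `-Inf` iff some unit has zero total
#'   mixture density), `grad_g` and `grad_h`.
#' @export
mixture_loglik <- function(g, h, comp) {
  stopifnot(inherits(comp, "component_loglik"))
  nk <- dim(comp$entries)[2]; L <- dim(comp$entries)[3]
  if (length(g) != nk) stop("'g' has length ", length(g), ", expected ", nk)
  if (length(h) != L) stop("'h' has length ", length(h), ", expected ", L)
  if (any(g < 0) || any(h < 0)) stop("'g' and 'h' must be nonnegative")
  # The sum-to-one condition is the caller's responsibility: the objective and
  # its gradient are well defined for any nonnegative weights, and evaluating
  # slightly off the simplex is what makes finite-difference gradient
  # verification possible.
  m <- comp$m
  M <- apply(comp$entries, 1, max)              # per-unit stabilizer
  M[!is.finite(M)] <- 0                         # all-(-Inf) unit: density 0
  P <- exp(comp$entries - array(M, dim(comp$entries)))  # m x nk x L
  A <- matrix(0, m, nk)                          # sum_l h_l P[, , l]
  H <- matrix(0, m, L)                           # sum_k g_k P[, , l]
  for (l in seq_len(L)) {
    Pl <- matrix(P[, , l], m, nk)
    A <- A + h[l] * Pl
    H[, l] <- Pl %*% g
  }
  den <- as.vector(A %*% g)
  loglik <- if (any(den == 0)) -Inf else sum(log(den) + M)
  inv <- ifelse(den > 0, 1 / den, NaN)
  list(loglik = loglik,
       grad_g = as.vector(crossprod(A, inv)),
       grad_h = as.vector(crossprod(H, inv)))
}
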