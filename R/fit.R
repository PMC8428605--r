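# Uniform-interval representation of unimodal pmfs on a symmetric grid.
#
# Every pmf g on indices -K..K that is nondecreasing up to the mode (index 0)
# and nonincreasing after it is a convex combination of discrete uniforms on
# intervals [lo, hi] with lo <= 0 <= hi (layer-cake decomposition). The basis
# matrix B maps interval weights w (length (K+1)^2) to g = B w, so any
# w in the simplex yields an exactly feasible g.
unimodal_basis <- function(K) {
  nk <- 2L * K + 1L
  ints <- expand.grid(lo = -K:0, hi = 0:K)
  J <- nrow(ints)
  B <- matrix(0, nk, J)
  for (j in seq_len(J)) {
    idx <- (ints$lo[j]:ints$hi[j]) + K + 1L
    B[idx, j] <- 1 / length(idx)
  }
  list(B = B, intervals = ints, J = J)
}

#' Control parameters for the two-mixture fit
#'
#' @param tol convergence tolerance: the fit is declared converged when the
#'   objective changes by less than `tol * (|loglik| + 1)` over one outer
#'   block-coordinate cycle. The default `1e-7` leaves the estimated mixing
#'   weights within about `1e-3` of a much deeper (`1e-10`) optimization at a
#'   fraction of the cost; tighten it when individual weights are of
#'   interest beyond the third decimal.
#' @param max_outer maximum number of outer cycles (one cycle = one full
#'   pass over the effect-weight block and the variance-weight block).
#' @param inner_cycles maximum accelerated-EM cycles per block per pass.
#' @param floor small positive mass floor applied when projecting an
#'   extrapolated iterate back onto the simplex, so that multiplicative
#'   updates can revive components.
#' @return list of class `"twomix_control"`.
#' @export
twomix_control <- function(tol = 1e-7, max_outer = 100L, inner_cycles = 50L,
                           floor = 1e-15) {
  stopifnot(tol > 0, max_outer >= 1, inner_cycles >= 1, floor >= 0)
  structure(list(tol = tol, max_outer = as.integer(max_outer),
                 inner_cycles = as.integer(inner_cycles), floor = floor),
            class = "twomix_control")
}

#' Uniform initialization of the mixing distributions
#'
#' @param egrid an [effect_grid()].
#' @param vgrid a [variance_grid()].
#' @return list with `g0` (uniform over the effect grid, which satisfies the
#'   unimodality ordering with equalities) and `h0` (uniform over the
#'   variance grid).
#' @export
init_mixing <- function(egrid, vgrid) {
  stopifnot(inherits(egrid, "effect_grid"), inherits(vgrid, "variance_grid"))
  nk <- length(egrid$values)
  list(g0 = rep(1 / nk, nk), h0 = rep(1 / vgrid$L, vgrid$L))
}

# Inner solver: accelerated EM on one block (mixture weights p for a fixed
# m x d matrix D of component densities, objective sum_i log (D p)_i).
# Each cycle is two EM steps plus a squared-extrapolation trial with a
# gradually growing step cap and a monotone fallback, so the objective never
# decreases. Returns the weights at a (near) stationary point of the concave
# block subproblem.
block_em <- function(p, D, m, max_cycles = 100L, step_tol = 1e-12,
                     floor = 1e-15) {
  upd <- function(p) {
    den <- as.vector(D %*% p)
    p <- p * as.vector(crossprod(D, 1 / den)) / m
    p / sum(p)
  }
  obj <- function(p) {
    den <- as.vector(D %*% p)
    if (any(den <= 0)) return(-Inf)
    sum(log(den))
  }
  l0 <- obj(p)
  step_max <- 1
  for (i in seq_len(max_cycles)) {
    p1 <- upd(p); p2 <- upd(p1)
    r <- p1 - p
    v <- p2 - p1 - r
    alpha <- -sqrt(sum(r^2)) / max(sqrt(sum(v^2)), 1e-300)
    alpha <- max(min(alpha, -1), -step_max)
    pn <- pmax(p - 2 * alpha * r + alpha^2 * v, floor)
    pn <- upd(pn / sum(pn))
    l1 <- obj(pn)
    if (!is.finite(l1) || l1 < l0) {
      pn <- p2
      l1 <- obj(p2)
      step_max <- max(1, step_max / 2)
    } else if (alpha == -step_max) {
      step_max <- 2 * step_max
    }
    moved <- sqrt(sum((pn - p)^2))
    p <- pn
    l0 <- l1
    if (moved < step_tol) break
  }
  p
}

#' Fit the two-mixture empirical Bayes model
#'
#' Maximizes the mixture log-likelihood over the product of two probability
#' simplices, with the unimodality ordering constraint on the effect mixing
#' distribution `g` (nondecreasing up to the grid mode, nonincreasing after).
#' The solver works in an exact reparameterization: any unimodal `g` is a
#' convex combination of discrete uniforms on grid intervals containing the
#' mode, so the constrained problem becomes an ordinary mixture MLE over
#' interval weights and variance weights, solved by blockwise EM with
#' squared-extrapolation (SQUAREM-type) acceleration and a monotone fallback.
#' Feasibility is exact by construction and the objective never decreases.
#'
#' @param x numeric vector of effect estimates, or a [summary_stats()] object,
#'   or a [grouped_matrix()] (reduced via [two_group_summary()]).
#' @param s2 squared standard errors (ignored when `x` is an object).
#' @param df shared degrees of freedom (ignored when `x` is an object).
#' @param s standard errors, alternative to `s2`.
#' @param unit_ids optional unit labels.
#' @param K effect grid half-size; the grid has `2K + 1` points. Default 15.
#' @param L variance grid size. Default 20 (estimates of the null mass
#'   stabilize once the variance grid is at least this fine; see the
#'   methods vignette).
#' @param mode effect grid mode (the point null), default 0.
#' @param subsample fraction of units used in the optimization (0 < f <= 1).
#'   Values below 1 use a seeded uniform random subset of `ceiling(f * m)`
#'   units to estimate (g, h); posterior quantities are still computed for
#'   all units. Requires `seed`.
#' @param seed integer seed for the subsample draw; required iff
#'   `subsample < 1`.
#' @param control a [twomix_control()] list.
#'
#' @return An object of class `"twomix"`: a list with the estimated mixing
#'   distributions `g` (effects) and `h` (variances), the grids `egrid` and
#'   `vgrid`, `loglik` and `loglik_init` (both on the fitting units),
#'   `converged`, `n_outer`, `constraint_violation`, `pi0` (mass of `g` at
#'   the mode), `posterior` (a `twomix_posterior` for all units, see
#'   [posterior_effects()]), the input `stats`, `subsample_idx`, and `call`.
#' @seealso [posterior_effects()], [discovery_list()], [estimate_pi0()],
#'   [verify_constraints()].
#' @export
#' @examples
#' set.seed(1)
#' m <- 200; n <- 5
#' y1 <- matrix(rnorm(m * n), m); y2 <- matrix(rnorm(m * n), m)
#' ss <- summary_stats(x = rowMeans(y2) - rowMeans(y1),
#'                     s2 = (apply(y1, 1, var) + apply(y2, 1, var)) / n,
#'                     df = 2 * n - 2)
#' fit <- twomix(ss, K = 5, L = 4)
#' estimate_pi0(fit)
twomix <- function(x, s2 = NULL, df = NULL, s = NULL, unit_ids = NULL,
                   K = 15, L = 20, mode = 0,
                   subsample = 1, seed = NULL,
                   control = twomix_control()) {
  cl <- match.call()
  stats <- if (inherits(x, "summary_stats")) x
           else if (inherits(x, "grouped_matrix")) two_group_summary(x)
           else summary_stats(x = x, s2 = s2, df = df, s = s, unit_ids = unit_ids)
  if (!inherits(control, "twomix_control")) control <- do.call(twomix_control, control)
  if (length(subsample) != 1L || subsample <= 0 || subsample > 1)
    stop("'subsample' must be in (0, 1]")

  egrid <- effect_grid(stats$x, K = K, mode = mode)
  vgrid <- variance_grid(stats$s2, L = L)

  sub_idx <- NULL
  fit_stats <- stats
  if (subsample < 1) {
    if (is.null(seed)) stop("'seed' is required when subsample < 1")
    n_sub <- ceiling(subsample * stats$m)
    sub_idx <- sort(with_seed(seed, sample.int(stats$m, n_sub)))
    fit_stats <- summary_stats(x = stats$x[sub_idx], s2 = stats$s2[sub_idx],
                               df = stats$df, unit_ids = stats$unit_ids[sub_idx])
  }

  comp <- component_loglik(fit_stats, egrid, vgrid)
  nk <- 2L * egrid$K + 1L
  Lg <- vgrid$L
  m <- fit_stats$m
  ub <- unimodal_basis(egrid$K)
  B <- ub$B; J <- ub$J

  M <- apply(comp$entries, 1, max)
  M[!is.finite(M)] <- 0
  Pm <- matrix(exp(comp$entries - array(M, dim(comp$entries))), m, nk * Lg)
  Msum <- sum(M)

  # uniform/uniform initialization (deterministic, exactly feasible)
  w <- rep(1 / J, J)
  h <- rep(1 / Lg, Lg)
  g <- as.vector(B %*% w)
  den0 <- as.vector(Pm %*% as.vector(outer(g, h)))
  if (any(den0 <= 0))
    stop("the mixture density is zero at initialization; check inputs")
  ll_init <- sum(log(den0)) + Msum

  # Block-coordinate ascent: with h fixed, the objective is concave in the
  # interval weights w (an ordinary mixture MLE), and symmetrically for h
  # with g fixed; each block is solved by accelerated EM. Both conditional
  # problems being concave, alternation converges to a stationary point of
  # the (possibly multimodal) joint objective, monotonically.
  l0 <- ll_init
  converged <- FALSE
  n_outer <- 0L
  for (it in seq_len(control$max_outer)) {
    n_outer <- it
    # A[i, k] = sum_l h_l P_ikl; the w-block sees the m x J matrix A %*% B
    A <- matrix(0, m, nk)
    for (l in seq_len(Lg))
      A <- A + h[l] * matrix(Pm[, ((l - 1) * nk + 1):(l * nk)], m, nk)
    w <- block_em(w, A %*% B, m, max_cycles = control$inner_cycles,
                  floor = control$floor)
    g <- as.vector(B %*% w)
    # Hm[i, l] = sum_k g_k P_ikl
    Hm <- matrix(0, m, Lg)
    for (l in seq_len(Lg))
      Hm[, l] <- matrix(Pm[, ((l - 1) * nk + 1):(l * nk)], m, nk) %*% g
    h <- block_em(h, Hm, m, max_cycles = control$inner_cycles,
                  floor = control$floor)
    l1 <- sum(log(as.vector(Hm %*% h))) + Msum
    if (abs(l1 - l0) < control$tol * (abs(l0) + 1)) {
      converged <- TRUE
      l0 <- l1
      break
    }
    l0 <- l1
  }

  g <- as.vector(B %*% w)
  g <- g / sum(g)
  h <- h / sum(h)

  fit <- structure(
    list(g = g, h = h, w = w, egrid = egrid, vgrid = vgrid,
         loglik = l0, loglik_init = ll_init,
         converged = converged, n_outer = n_outer,
         pi0 = g[egrid$mode_index],
         stats = stats, subsample_idx = sub_idx, seed = seed,
         control = control, call = cl),
    class = "twomix"
  )
  fit$constraint_violation <- max(verify_constraints(fit)$max_simplex_violation,
                                  verify_constraints(fit)$max_order_violation)
  fit$posterior <- posterior_effects(fit, stats)
  fit
}

#' Verify the simplex and unimodality constraints of a fit
#'
#' Exact arithmetic over the stored mixing vectors: nonnegativity, unit sums,
#' and the ordering constraints on `g` (nondecreasing up to the mode index,
#' nonincreasing after).
#'
#' @param fit a `"twomix"` object, or a numeric vector `g` (then `h` and
#'   `mode_index` must be supplied).
#' @param h variance mixing vector (when `fit` is a raw `g` vector).
#' @param mode_index index of the mode in `g` (when `fit` is a raw vector).
#' @param tol tolerance for the `ok` verdict. Default `1e-8`.
#' @return list with `max_simplex_violation`, `max_order_violation`, `ok`.
#' @export
verify_constraints <- function(fit, h = NULL, mode_index = NULL, tol = 1e-8) {
  if (inherits(fit, "twomix")) {
    g <- fit$g; h <- fit$h; mode_index <- fit$egrid$mode_index
  } else {
    g <- as.numeric(fit)
    if (is.null(h) || is.null(mode_index))
      stop("'h' and 'mode_index' are required when passing a raw 'g' vector")
  }
  simplex_viol <- max(abs(sum(g) - 1), abs(sum(h) - 1),
                      -min(g, 0), -min(h, 0))
  up <- if (mode_index > 1) diff(g[seq_len(mode_index)]) else numeric()
  down <- if (mode_index < length(g)) diff(g[mode_index:length(g)]) else numeric()
  order_viol <- max(0, -up, down)
  list(max_simplex_violation = simplex_viol,
       max_order_violation = order_viol,
       ok = simplex_viol <= tol && order_viol <= tol)
}

# All compositions of n into p nonnegative parts, as a (count x p) matrix.
compositions <- function(n, p) {
  if (p == 1L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- compositions(n - first, p - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Brute-force mesh search for the two-mixture MLE on tiny grids
#'
#' Exhaustively enumerates all probability vectors on a regular mesh of both
#' simplices (step `step`), keeps only unimodal `g`, and returns the mesh
#' pair maximizing the mixture log-likelihood. Intended as an independent
#' reference for validating the main solver on small problems; refuses
#' combinatorially large inputs.
#'
#' @param stats a [summary_stats()] object.
#' @param egrid an [effect_grid()] with at most 5 points.
#' @param vgrid a [variance_grid()] with at most 2 points.
#' @param step mesh step; `1/step` must be an integer. Default 0.01.
#' @param max_candidates guard on the number of (g, h) pairs evaluated.
#' @return list with `g`, `h`, `loglik`.
#' @export
mesh_fit <- function(stats, egrid, vgrid, step = 0.01, max_candidates = 2e6) {
  stopifnot(inherits(stats, "summary_stats"),
            inherits(egrid, "effect_grid"), inherits(vgrid, "variance_grid"))
  nk <- length(egrid$values); L <- vgrid$L
  if (nk > 5L || L > 2L) stop("mesh_fit only supports grids with <= 5 effect points and <= 2 variance points")
  n_step <- round(1 / step)
  if (abs(n_step * step - 1) > 1e-9) stop("'step' must divide 1")

  Gm <- compositions(n_step, nk) / n_step
  mode_idx <- egrid$mode_index
  keep <- rep(TRUE, nrow(Gm))
  if (mode_idx > 1L)
    keep <- keep & apply(Gm[, seq_len(mode_idx), drop = FALSE], 1,
                         function(r) all(diff(r) >= 0))
  if (mode_idx < nk)
    keep <- keep & apply(Gm[, mode_idx:nk, drop = FALSE], 1,
                         function(r) all(diff(r) <= 0))
  Gm <- Gm[keep, , drop = FALSE]
  Hm <- if (L == 1L) matrix(1, 1, 1) else compositions(n_step, L) / n_step
  if (nrow(Gm) * nrow(Hm) > max_candidates)
    stop("mesh too large (", nrow(Gm) * nrow(Hm), " candidates); refuse")

  comp <- component_loglik(stats, egrid, vgrid)
  M <- apply(comp$entries, 1, max); M[!is.finite(M)] <- 0
  Pm <- matrix(exp(comp$entries - array(M, dim(comp$entries))), stats$m, nk * L)
  Msum <- sum(M)

  best <- list(loglik = -Inf)
  for (jh in seq_len(nrow(Hm))) {
    h <- Hm[jh, ]
    A <- matrix(0, stats$m, nk)    # sum_l h_l P_ikl
    for (l in seq_len(L))
      A <- A + h[l] * matrix(Pm[, ((l - 1) * nk + 1):(l * nk)], stats$m, nk)
    den <- A %*% t(Gm)             # m x candidates
    lls <- colSums(log(den)) + Msum
    jbest <- which.max(lls)
    if (lls[jbest] > best$loglik)
      best <- list(g = Gm[jbest, ], h = h, loglik = lls[jbest])
  }
  best
}
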