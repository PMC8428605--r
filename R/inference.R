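#' Per-unit posterior effect distributions, lfdr and lfsr
#'
#' For a fitted model, computes for each unit the posterior distribution of
#' its latent effect over the effect grid,
#' `P(theta_i = a_k | x_i, s2_i) proportional to
#' g_k * sum_l h_l p(x_i, s2_i | a_k, b_l)`,
#' normalized over the grid. The local false discovery rate is the posterior
#' mass at the grid mode (the point null); the local false sign rate is the
#' smaller of the two signed cumulative masses, both of which include the
#' mode:
#' `lfsr_i = min(P(theta_i <= a_0 | data), P(theta_i >= a_0 | data))`.
#'
#' @param fit a `"twomix"` object.
#' @param stats a [summary_stats()] object to evaluate; defaults to the data
#'   the model was fitted to. Must share the fit's `df` convention.
#' @return An object of class `"twomix_posterior"`: list with `unit_ids`,
#'   `P` (an `m x (2K+1)` matrix of posterior masses; rows sum to 1),
#'   `lfdr`, `lfsr`, `egrid` and `mode_index`.
#' @export
posterior_effects <- function(fit, stats = NULL) {
  stopifnot(inherits(fit, "twomix"))
  if (is.null(stats)) stats <- fit$stats
  stopifnot(inherits(stats, "summary_stats"))
  comp <- component_loglik(stats, fit$egrid, fit$vgrid)
  m <- stats$m
  nk <- length(fit$egrid$values)
  L <- fit$vgrid$L
  M <- apply(comp$entries, 1, max)
  M[!is.finite(M)] <- 0
  P3 <- exp(comp$entries - array(M, dim(comp$entries)))
  A <- matrix(0, m, nk)
  for (l in seq_len(L))
    A <- A + fit$h[l] * matrix(P3[, , l], m, nk)
  numer <- sweep(A, 2, fit$g, `*`)
  den <- rowSums(numer)
  if (any(den <= 0 | !is.finite(den))) {
    bad <- stats$unit_ids[den <= 0 | !is.finite(den)]
    stop("zero posterior density for unit(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  P <- numer / den
  mi <- fit$egrid$mode_index
  lfdr <- P[, mi]
  lfsr <- pmin(rowSums(P[, seq_len(mi), drop = FALSE]),
               rowSums(P[, mi:nk, drop = FALSE]))
  structure(
    list(unit_ids = stats$unit_ids, P = P, lfdr = lfdr, lfsr = lfsr,
         egrid = fit$egrid, mode_index = mi),
    class = "twomix_posterior"
  )
}

#' @export
print.twomix_posterior <- function(x, ...) {
  cat("Posterior effect distributions for", length(x$lfdr), "units\n")
  cat("  lfdr: ", paste(signif(stats::quantile(x$lfdr, c(0, .5, 1)), 3),
                        collapse = " / "), "(min/med/max)\n")
  cat("  lfsr: ", paste(signif(stats::quantile(x$lfsr, c(0, .5, 1)), 3),
                        collapse = " / "), "(min/med/max)\n")
  invisible(x)
}

#' Threshold a posterior into a discovery list
#'
#' Selects the units whose lfdr (or lfsr) does not exceed `alpha`:
#' `{ i : statistic_i <= alpha }`. The mean lfdr over the list is attached as
#' a per-list FDR estimate (the expected rate of false discoveries in the
#' list is dominated by the threshold).
#'
#' @param post a `"twomix_posterior"` (or a `"twomix"` fit, whose stored
#'   posterior is used).
#' @param alpha threshold level in `[0, 1]`. Default 0.1.
#' @param statistic `"lfdr"` (default) or `"lfsr"`.
#' @return An object of class `"discovery_list"`: list with `indices`, `ids`,
#'   `threshold`, `statistic`, `n`, and `fdr_estimate` (mean lfdr over the
#'   list; `NA` when empty).
#' @export
discovery_list <- function(post, alpha = 0.1, statistic = c("lfdr", "lfsr")) {
  if (inherits(post, "twomix")) post <- post$posterior
  stopifnot(inherits(post, "twomix_posterior"))
  statistic <- match.arg(statistic)
  if (length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be in [0, 1]")
  stat <- post[[statistic]]
  idx <- which(stat <= alpha)
  structure(
    list(indices = idx, ids = post$unit_ids[idx],
         threshold = alpha, statistic = statistic, n = length(idx),
         fdr_estimate = if (length(idx)) mean(post$lfdr[idx]) else NA_real_),
    class = "discovery_list"
  )
}

#' @export
print.discovery_list <- function(x, ...) {
  cat(x$n, "discoveries at", x$statistic, "<=", x$threshold)
  if (!is.na(x$fdr_estimate))
    cat(" (estimated FDR ", signif(x$fdr_estimate, 3), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Estimated null proportion
#'
#' The marginal prior probability of a null effect, `pi0 = P(theta_i = a_0)`,
#' read off as the estimated effect mixing mass at the grid mode.
#'
#' @param fit a `"twomix"` object.
#' @return scalar in `[0, 1]`.
#' @export
estimate_pi0 <- function(fit) {
  stopifnot(inherits(fit, "twomix"))
  unname(fit$g[fit$egrid$mode_index])
}

#' Cross-study reproducibility of two discovery lists
#'
#' For discovery lists from two independent studies over a shared unit
#' universe, reports the number of units found in both and the common
#' fraction (Jaccard index) `|A intersect B| / |A union B|`.
#'
#' @param listA,listB `"discovery_list"` objects or plain id vectors.
#' @return list with `n_common` and `common_fraction` (`NA` when both lists
#'   are empty).
#' @export
#' @examples
#' overlap_metrics(c("A", "B", "C"), c("B", "C", "D"))  # 2, 0.5
overlap_metrics <- function(listA, listB) {
  ids <- function(l) if (inherits(l, "discovery_list")) l$ids else as.character(l)
  a <- unique(ids(listA)); b <- unique(ids(listB))
  n_common <- length(intersect(a, b))
  n_union <- length(union(a, b))
  list(n_common = n_common,
       common_fraction = if (n_union == 0) NA_real_ else n_common / n_union)
}
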