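# Shared test fixtures: small, fast synthetic instances.

# Deterministic small summary-statistics object.
make_stats <- function(m = 40, seed = 7, df = 6) {
  set.seed(seed)
  summary_stats(x = rnorm(m, 0, 1.5),
                s2 = rchisq(m, df) / df,
                df = df)
}

# Minimal twomix-shaped object with prescribed mixing vectors, for testing
# posterior computations under controlled priors without running the solver.
fake_fit <- function(g, h, stats, egrid = NULL, vgrid = NULL) {
  egrid <- egrid %||% effect_grid(stats$x, K = (length(g) - 1L) / 2L)
  vgrid <- vgrid %||% variance_grid(stats$s2, L = length(h))
  structure(list(g = g, h = h, egrid = egrid, vgrid = vgrid, stats = stats),
            class = "twomix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive (reference) mixture log-likelihood, computed without stabilization
# tricks: direct double sum in ordinary arithmetic.
naive_loglik <- function(g, h, stats, egrid, vgrid) {
  total <- 0
  for (i in seq_len(stats$m)) {
    den <- 0
    for (k in seq_along(egrid$values))
      for (l in seq_along(vgrid$values))
        den <- den + g[k] * h[l] *
          exp(normal_component_logpdf(stats$x[i], egrid$values[k], vgrid$values[l]) +
              scaled_chisq_logpdf(stats$s2[i], vgrid$values[l], stats$df))
    total <- total + log(den)
  }
  total
}
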