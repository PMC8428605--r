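test_that("scaled chi-square log-density matches closed forms", {
  # nu = 2: f(s2 | b) = (nu/b) * chisq_2(nu s2 / b) = (2/b) * e^{-s2/b} / 2
  expect_equal(scaled_chisq_logpdf(1, 1, 2), -1.0)
  expect_equal(scaled_chisq_logpdf(2, 2, 2), -1 + log(1 / 2),
               tolerance = 1e-12)

  # scale equivariance: doubling both s2 and b shifts the log-density by
  # log(1/2), for any degrees of freedom
  for (nu in c(1, 2, 7, 18))
    expect_equal(scaled_chisq_logpdf(2, 2, nu),
                 scaled_chisq_logpdf(1, 1, nu) + log(1 / 2),
                 tolerance = 1e-12)

  # integrates to 1 over s2 for fixed b, nu
  q <- integrate(function(s2) exp(scaled_chisq_logpdf(s2, b = 1.7, df = 5)),
                 0, Inf)
  expect_equal(q$value, 1, tolerance = 1e-6)

  expect_error(scaled_chisq_logpdf(-1, 1, 2), "> 0")
  expect_error(scaled_chisq_logpdf(1, 0, 2), "> 0")
})

test_that("normal component log-density matches closed forms", {
  expect_equal(normal_component_logpdf(0, 0, 1), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(normal_component_logpdf(0, 0, 1), -0.91894, tolerance = 1e-5)
  expect_equal(normal_component_logpdf(1, 0, 1), -1.41894, tolerance = 1e-5)
  expect_equal(normal_component_logpdf(0, 0, 4), log(1 / sqrt(8 * pi)),
               tolerance = 1e-12)
  expect_equal(normal_component_logpdf(0, 0, 4), -1.61209, tolerance = 1e-5)
})

test_that("component log-likelihood table sums the two factors", {
  ss <- summary_stats(x = 0, s2 = 1, df = 2)
  eg <- effect_grid(c(-1, 1), K = 1)          # values -1, 0, 1
  vg <- variance_grid(c(0.5, 1.5), L = 2)     # values 0.5, 1.5
  comp <- component_loglik(ss, eg, vg)
  expect_equal(dim(comp$entries), c(1, 3, 2))
  for (k in 1:3) for (l in 1:2)
    expect_equal(comp$entries[1, k, l],
                 normal_component_logpdf(0, eg$values[k], vg$values[l]) +
                 scaled_chisq_logpdf(1, vg$values[l], 2),
                 tolerance = 1e-12)

  # the worked single-entry value at (a = 0, b = 1)
  vg1 <- variance_grid(c(1, 1), L = 1)
  expect_equal(vg1$values, 1)
  comp1 <- component_loglik(ss, eg, vg1)
  expect_equal(comp1$entries[1, 2, 1], -1.91894, tolerance = 1e-5)
})

test_that("mixture log-likelihood matches naive computation and is additive", {
  ss <- make_stats(m = 12, seed = 3, df = 4)
  eg <- effect_grid(ss$x, K = 2)
  vg <- variance_grid(ss$s2, L = 3)
  comp <- component_loglik(ss, eg, vg)
  g <- c(0.05, 0.2, 0.5, 0.2, 0.05)
  h <- c(0.3, 0.4, 0.3)
  ml <- mixture_loglik(g, h, comp)
  expect_equal(ml$loglik, naive_loglik(g, h, ss, eg, vg), tolerance = 1e-10)

  # degenerate mixture recovers the single component entry
  ss1 <- summary_stats(x = 0, s2 = 1, df = 2)
  eg1 <- effect_grid(c(-1, 1), K = 1)
  vg1 <- variance_grid(c(1, 1), L = 1)
  comp1 <- component_loglik(ss1, eg1, vg1)
  ml1 <- mixture_loglik(c(0, 1, 0), 1, comp1)
  expect_equal(ml1$loglik, comp1$entries[1, 2, 1], tolerance = 1e-12)

  # duplicating every unit doubles the log-likelihood
  ss2 <- summary_stats(x = rep(ss$x, 2), s2 = rep(ss$s2, 2), df = ss$df)
  comp2 <- component_loglik(ss2, eg, vg)
  expect_equal(mixture_loglik(g, h, comp2)$loglik, 2 * ml$loglik,
               tolerance = 1e-10)

  expect_error(mixture_loglik(g[-1], h, comp), "length")
  expect_error(mixture_loglik(g, c(h, 0.1), comp), "length")
  expect_error(mixture_loglik(-g, h, comp), "nonnegative")
})

test_that("analytic gradients match central finite differences", {
  ss <- make_stats(m = 15, seed = 5, df = 6)
  eg <- effect_grid(ss$x, K = 3)
  vg <- variance_grid(ss$s2, L = 3)
  comp <- component_loglik(ss, eg, vg)
  set.seed(11)
  eps <- 1e-6
  for (draw in 1:5) {
    g <- rgamma(7, 1); g <- g / sum(g)
    h <- rgamma(3, 1); h <- h / sum(h)
    ml <- mixture_loglik(g, h, comp)
    for (k in sample(7, 3)) {
      gp <- g; gp[k] <- gp[k] + eps
      gm <- g; gm[k] <- gm[k] - eps
      fd <- (mixture_loglik(gp, h, comp)$loglik -
             mixture_loglik(gm, h, comp)$loglik) / (2 * eps)
      expect_equal(ml$grad_g[k], fd, tolerance = 1e-6)
    }
    for (l in 1:3) {
      hp <- h; hp[l] <- hp[l] + eps
      hm <- h; hm[l] <- hm[l] - eps
      fd <- (mixture_loglik(g, hp, comp)$loglik -
             mixture_loglik(g, hm, comp)$loglik) / (2 * eps)
      expect_equal(ml$grad_h[l], fd, tolerance = 1e-6)
    }
  }
})

test_that("mixture log-likelihood is permutation- and bound-consistent", {
  ss <- make_stats(m = 10, seed = 9, df = 4)
  eg <- effect_grid(ss$x, K = 2)
  vg <- variance_grid(ss$s2, L = 2)
  comp <- component_loglik(ss, eg, vg)
  g1 <- c(0.1, 0.2, 0.4, 0.2, 0.1); h1 <- c(0.5, 0.5)
  g2 <- c(0, 0.3, 0.4, 0.3, 0);     h2 <- c(0.2, 0.8)

  # reordering units leaves the value unchanged
  perm <- c(4, 1, 10, 2, 8, 3, 9, 5, 7, 6)
  ssp <- summary_stats(x = ss$x[perm], s2 = ss$s2[perm], df = ss$df)
  compp <- component_loglik(ssp, eg, vg)
  expect_equal(mixture_loglik(g1, h1, comp)$loglik,
               mixture_loglik(g1, h1, compp)$loglik, tolerance = 1e-12)

  # the objective is concave along segments in (g, h) jointly mixed the same
  # way on both simplices: value at the midpoint is at least the chord value
  lmid <- mixture_loglik((g1 + g2) / 2, h1, comp)$loglik
  expect_gte(lmid, (mixture_loglik(g1, h1, comp)$loglik +
                    mixture_loglik(g2, h1, comp)$loglik) / 2 - 1e-10)
})
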