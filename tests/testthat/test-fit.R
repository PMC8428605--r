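test_that("unimodal basis spans exactly the unimodal simplex", {
  ub <- twomix:::unimodal_basis(3)
  expect_equal(dim(ub$B), c(7, 16))
  expect_equal(colSums(ub$B), rep(1, 16))    # every column is a pmf
  # every basis column is unimodal about the centre
  for (j in seq_len(ub$J)) {
    v <- twomix::verify_constraints(ub$B[, j], h = 1, mode_index = 4)
    expect_true(v$ok)
  }
  # random convex combinations stay unimodal, exactly
  set.seed(2)
  for (r in 1:10) {
    w <- rgamma(16, 1); w <- w / sum(w)
    g <- as.vector(ub$B %*% w)
    v <- verify_constraints(g, h = 1, mode_index = 4, tol = 1e-12)
    expect_true(v$ok)
  }
})

test_that("verify_constraints flags ordering violations", {
  ok <- verify_constraints(c(0.1, 0.2, 0.4, 0.2, 0.1), h = 1, mode_index = 3)
  expect_true(ok$ok)
  bad <- verify_constraints(c(0.3, 0.1, 0.2, 0.1, 0.3), h = 1, mode_index = 3)
  expect_false(bad$ok)
  expect_gte(bad$max_order_violation, 0.2 - 1e-12)
  nosum <- verify_constraints(c(0.2, 0.4, 0.2), h = 1, mode_index = 2)
  expect_false(nosum$ok)
  expect_gte(nosum$max_simplex_violation, 0.2 - 1e-12)
  expect_error(verify_constraints(c(0.5, 0.5)), "required")
})

test_that("init_mixing is uniform and feasible", {
  ss <- make_stats(m = 10)
  eg <- effect_grid(ss$x, K = 4)
  vg <- variance_grid(ss$s2, L = 3)
  ini <- init_mixing(eg, vg)
  expect_equal(ini$g0, rep(1 / 9, 9))
  expect_equal(ini$h0, rep(1 / 3, 3))
  expect_true(verify_constraints(ini$g0, ini$h0, eg$mode_index)$ok)
})

test_that("mesh refinement never decreases the best objective", {
  ss <- make_stats(m = 25, seed = 13, df = 4)
  eg <- effect_grid(ss$x, K = 1)
  vg <- variance_grid(ss$s2, L = 1)
  coarse <- mesh_fit(ss, eg, vg, step = 0.05)
  fine <- mesh_fit(ss, eg, vg, step = 0.01)
  expect_gte(fine$loglik, coarse$loglik)
  # refusal on combinatorially large inputs
  eg_big <- effect_grid(ss$x, K = 5)
  expect_error(mesh_fit(ss, eg_big, vg), "<= 5 effect points")
})

test_that("solver attains the mesh-oracle objective on tiny grids", {
  ss <- make_stats(m = 30, seed = 21, df = 6)
  eg <- effect_grid(ss$x, K = 1)
  for (L in 1:2) {
    vg <- variance_grid(ss$s2, L = L)
    oracle <- mesh_fit(ss, eg, vg, step = 0.01)
    fit <- twomix(ss, K = 1, L = L)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("the fit improves on its initialization and satisfies constraints", {
  ss <- make_stats(m = 60, seed = 17, df = 6)
  fit <- twomix(ss, K = 5, L = 4)
  expect_s3_class(fit, "twomix")
  expect_gte(fit$loglik, fit$loglik_init)
  expect_true(fit$converged)
  v <- verify_constraints(fit)
  expect_true(v$ok)
  expect_lte(fit$constraint_violation, 1e-8)
  expect_equal(sum(fit$g), 1, tolerance = 1e-12)
  expect_equal(sum(fit$h), 1, tolerance = 1e-12)
  expect_equal(fit$pi0, fit$g[fit$egrid$mode_index])
})

test_that("the attained objective is stable under unit reordering", {
  ss <- make_stats(m = 50, seed = 19, df = 6)
  set.seed(1); perm <- sample(ss$m)
  ssp <- summary_stats(x = ss$x[perm], s2 = ss$s2[perm], df = ss$df)
  f1 <- twomix(ss, K = 4, L = 3)
  f2 <- twomix(ssp, K = 4, L = 3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$g, f2$g, tolerance = 1e-4)
})

test_that("subsampled fits are seeded, reproducible and close to full fits", {
  set.seed(31)
  m <- 400
  theta <- ifelse(runif(m) < 0.8, 0, rnorm(m, 0, 1.5))
  ss <- summary_stats(x = rnorm(m, theta, 0.5), s2 = 0.25 * rchisq(m, 8) / 8,
                      df = 8)
  expect_error(twomix(ss, K = 4, L = 3, subsample = 0.5), "seed")
  fa <- twomix(ss, K = 4, L = 3, subsample = 0.5, seed = 5)
  fb <- twomix(ss, K = 4, L = 3, subsample = 0.5, seed = 5)
  expect_identical(fa$subsample_idx, fb$subsample_idx)
  expect_equal(fa$g, fb$g)
  expect_length(fa$posterior$lfdr, m)          # posterior covers all units
  full <- twomix(ss, K = 4, L = 3)
  expect_lte(abs(fa$pi0 - full$pi0), 0.1)
  expect_error(twomix(ss, subsample = 1.2), "must be in", fixed = TRUE)
})

test_that("grouped matrices and raw vectors are accepted as inputs", {
  set.seed(41)
  gm <- grouped_matrix(matrix(rnorm(30 * 8), 30), labels = rep(1:2, each = 4))
  f1 <- twomix(gm, K = 3, L = 2)
  f2 <- twomix(two_group_summary(gm), K = 3, L = 2)
  expect_equal(f1$loglik, f2$loglik)
  ss <- two_group_summary(gm)
  f3 <- twomix(ss$x, s2 = ss$s2, df = ss$df, K = 3, L = 2)
  expect_equal(f3$loglik, f1$loglik)
})
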