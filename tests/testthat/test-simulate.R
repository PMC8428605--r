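test_that("scenarios validate their configuration", {
  sp <- scenario("near_normal", pi0 = 0.9, m = 100, n_per_group = 5)
  expect_s3_class(sp, "scenario")
  expect_equal(sp$m, 100L)
  expect_error(scenario("nope"), "arg")
  expect_error(scenario("spiky", pi0 = 1.5), "pi0")
  expect_error(scenario("spiky", n_per_group = 1), "n_per_group")
  # custom alternative shapes are accepted and validated
  alt <- data.frame(weight = c(0.5, 0.5), mean = c(-1, 1), sd = c(1, 1))
  expect_s3_class(scenario("bimodal", alt = alt), "scenario")
  bad <- data.frame(weight = c(0.5, 0.6), mean = 0, sd = 1)
  expect_error(scenario("bimodal", alt = bad))
})

test_that("effect sampling respects the null mass", {
  sp <- scenario("near_normal", m = 100)
  # pi0 = 1: all null
  th1 <- sample_effects(sp, m = 500, pi0 = 1, seed = 1)
  expect_true(all(th1 == 0))
  # pi0 = 0: continuous alternative, zeros have probability 0
  th0 <- sample_effects(sp, m = 500, pi0 = 0, seed = 1)
  expect_true(all(th0 != 0))
  # pi0 = 0.5, m = 10000: zero-count inside the central 99% binomial interval
  th <- sample_effects(sp, m = 10000, pi0 = 0.5, seed = 7)
  n0 <- sum(th == 0)
  expect_gte(n0, qbinom(0.005, 10000, 0.5))
  expect_lte(n0, qbinom(0.995, 10000, 0.5))
  # random-pi0 scenarios require an explicit pi0 here
  expect_error(sample_effects(scenario("spiky"), m = 10), "pi0")
})

test_that("variance models generate from the right laws", {
  expect_equal(sample_variances(variance_model("point_mass", v = 2), 5),
               rep(2, 5))
  tv <- sample_variances(variance_model("two_point", v1 = 0.5, v2 = 2, w = 0.5),
                         200, seed = 2)
  expect_true(all(tv %in% c(0.5, 2)))
  # inverse-gamma(shape 5, scale 4) has mean scale/(shape-1) = 1
  ig <- sample_variances(variance_model("inverse_gamma", shape = 5, scale = 4),
                         20000, seed = 3)
  expect_true(all(ig > 0))
  expect_lte(abs(mean(ig) - 1), 0.05)
  expect_error(variance_model("point_mass", v = -1))
})

test_that("simulated studies carry the design degrees of freedom and are seeded", {
  sp <- scenario("near_normal", pi0 = 0.8, m = 50, n_per_group = 7)
  sim <- simulate_dataset(sp, seed = 5)
  expect_equal(sim$stats$df, 2 * 7 - 2)
  expect_equal(sim$stats$m, 50L)
  expect_equal(sim$pi0, 0.8)
  sim2 <- simulate_dataset(sp, seed = 5)
  expect_identical(sim$stats$x, sim2$stats$x)
  sim3 <- simulate_dataset(sp, seed = 6)
  expect_false(identical(sim$stats$x, sim3$stats$x))
  expect_error(simulate_dataset(sp), "seed")
  # random-pi0 scenario draws pi0 in [0.5, 1]
  spr <- scenario("spiky", m = 20, n_per_group = 3)
  simr <- simulate_dataset(spr, seed = 9)
  expect_gte(simr$pi0, 0.5)
  expect_lte(simr$pi0, 1)
})

test_that("effect estimates are unbiased for the latent effects", {
  sp <- scenario("near_normal", pi0 = 0.7, m = 100, n_per_group = 4)
  devs <- unlist(lapply(1:200, function(r) {
    sim <- simulate_dataset(sp, seed = 1000 + r)
    sim$stats$x - sim$theta
  }))
  se <- sd(devs) / sqrt(length(devs))
  expect_lte(abs(mean(devs)), 3 * se)
})

test_that("empirical FDP follows the convention for empty lists", {
  theta <- c(0, 1, 0, 2)
  expect_equal(empirical_fdp(integer(0), theta), 0)
  expect_equal(empirical_fdp(c(1L, 2L), theta), 0.5)
  expect_equal(empirical_fdp(c(2L, 4L), theta), 0)
  expect_error(empirical_fdp(5L, theta), "cover")
})

test_that("1-Wasserstein distance matches closed forms", {
  expect_equal(wasserstein1(0, 1, 0, 1), 0)
  expect_equal(wasserstein1(0, 1, 1, 1), 1)
  expect_equal(wasserstein1(c(0, 1), c(0.5, 0.5), 0, 1), 0.5)
  # translation-invariance of the spread: d(delta_a, delta_b) = |a - b|
  expect_equal(wasserstein1(2.5, 1, -1, 1), 3.5)
  # symmetry
  x1 <- c(-1, 0, 2); p1 <- c(0.2, 0.5, 0.3)
  x2 <- c(0, 1);     p2 <- c(0.6, 0.4)
  expect_equal(wasserstein1(x1, p1, x2, p2), wasserstein1(x2, p2, x1, p1))
  # identical distributions written on different supports
  expect_equal(wasserstein1(c(0, 1), c(1, 0), c(0, 5), c(1, 0)), 0)
  expect_error(wasserstein1(0, 1, 0, 0.5), "masses differ")
})

test_that("operating characteristics aggregate replicates and strata", {
  sp <- scenario("near_normal", pi0 = 0.9, m = 120, n_per_group = 5)
  oc <- run_operating_characteristics(sp, reps = 3, seed = 31, K = 4, L = 3)
  expect_s3_class(oc, "twomix_oc")
  expect_equal(nrow(oc$replicates), 3L)
  expect_equal(oc$n_failed, 0L)
  expect_true(all(c("pi0", "pi0_hat", "wasserstein",
                    "fdp_0.05", "n_disc_0.05") %in% names(oc$replicates)))
  expect_true(all(oc$replicates$wasserstein >= 0))
  expect_true(all(oc$replicates$fdp_0.05 >= 0 & oc$replicates$fdp_0.05 <= 1))
  # fixed pi0 = 0.9 falls in the (0.875, 1] stratum only
  expect_true(all(grepl("0.875", oc$by_stratum$stratum)))
  # reproducible under the same master seed
  oc2 <- run_operating_characteristics(sp, reps = 3, seed = 31, K = 4, L = 3)
  expect_equal(oc$replicates$pi0_hat, oc2$replicates$pi0_hat)
  expect_error(run_operating_characteristics(sp, reps = 2), "seed")
})
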