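# Normal-mixture parameterizations of the named alternative effect shapes,
# following the adaptive-shrinkage simulation literature. Each is symmetric
# about 0; all are overridable through scenario(alt = ...).
alt_shapes <- function() {
  list(
    spiky = data.frame(weight = c(0.4, 0.2, 0.2, 0.2),
                       mean = 0, sd = c(0.25, 0.5, 1, 2)),
    near_normal = data.frame(weight = c(2/3, 1/3), mean = 0, sd = c(1, 2)),
    flattop = data.frame(weight = rep(1/7, 7),
                         mean = seq(-1.5, 1.5, by = 0.5), sd = 0.5),
    big_variance = data.frame(weight = 1, mean = 0, sd = 4),
    bimodal = data.frame(weight = c(0.5, 0.5), mean = c(-2, 2), sd = c(1, 1))
  )
}

#' Generative model for the latent variances
#'
#' @param type `"point_mass"` (all variances equal `v`), `"two_point"`
#'   (value `v1` with probability `w`, else `v2`), or `"inverse_gamma"`
#'   (inverse-gamma with the given `shape` and `scale`; mean
#'   `scale / (shape - 1)`).
#' @param v,v1,v2,w,shape,scale model parameters, all variances/scales > 0,
#'   `0 <= w <= 1`.
#' @return An object of class `"variance_model"`.
#' @export
#' @examples
#' variance_model("point_mass", v = 1)
#' variance_model("inverse_gamma", shape = 5, scale = 4)  # mean 1
variance_model <- function(type = c("point_mass", "two_point", "inverse_gamma"),
                           v = 1, v1 = 0.5, v2 = 2, w = 0.5,
                           shape = 5, scale = 4) {
  type <- match.arg(type)
  pars <- switch(type,
    point_mass = { stopifnot(v > 0); list(v = v) },
    two_point = {
      stopifnot(v1 > 0, v2 > 0, w >= 0, w <= 1)
      list(v1 = v1, v2 = v2, w = w)
    },
    inverse_gamma = { stopifnot(shape > 0, scale > 0); list(shape = shape, scale = scale) }
  )
  structure(c(list(type = type), pars), class = "variance_model")
}

#' Simulation scenario for operating-characteristic studies
#'
#' Defines a generative configuration: latent effects
#' `theta_i ~ pi0 * delta_0 + (1 - pi0) * g_alt` with a named alternative
#' shape, latent variances from a [variance_model()], and Gaussian
#' observations per group.
#'
#' @param name alternative shape: `"spiky"`, `"near_normal"`, `"flattop"`,
#'   `"big_variance"` or `"bimodal"`.
#' @param pi0 null mass in `[0, 1]`, or `NULL` to draw a fresh
#'   `pi0 ~ U(0.5, 1)` for each simulated dataset.
#' @param m number of testing units. Default 1000.
#' @param n_per_group Gaussian samples per group. Default 10.
#' @param variance_model a [variance_model()]; default point mass at 1
#'   (unit-variance Gaussian samples).
#' @param alt optional data frame (`weight`, `mean`, `sd`) overriding the
#'   named alternative's normal-mixture components.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name = c("spiky", "near_normal", "flattop",
                              "big_variance", "bimodal"),
                     pi0 = NULL, m = 1000, n_per_group = 10,
                     variance_model = twomix::variance_model("point_mass", v = 1),
                     alt = NULL) {
  name <- match.arg(name)
  if (!is.null(pi0)) stopifnot(length(pi0) == 1L, pi0 >= 0, pi0 <= 1)
  stopifnot(m >= 1, n_per_group >= 2, inherits(variance_model, "variance_model"))
  if (is.null(alt)) alt <- alt_shapes()[[name]]
  stopifnot(is.data.frame(alt), all(c("weight", "mean", "sd") %in% names(alt)),
            all(alt$weight >= 0), abs(sum(alt$weight) - 1) < 1e-8,
            all(alt$sd > 0))
  structure(
    list(name = name, pi0 = pi0, m = as.integer(m),
         n_per_group = as.integer(n_per_group),
         variance_model = variance_model, alt = alt),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': m = ", x$m, ", n/group = ", x$n_per_group,
      ", pi0 = ", if (is.null(x$pi0)) "U(0.5, 1)" else x$pi0,
      ", variances: ", x$variance_model$type, "\n", sep = "")
  invisible(x)
}

#' Sample latent effects from a scenario
#'
#' Each effect is 0 with probability `pi0` and otherwise drawn from the
#' scenario's alternative normal mixture.
#'
#' @param spec a [scenario()].
#' @param m number of draws; defaults to `spec$m`.
#' @param pi0 null mass override; required when the scenario leaves `pi0`
#'   random (`NULL`).
#' @param seed optional seed.
#' @return numeric vector of effects.
#' @export
sample_effects <- function(spec, m = spec$m, pi0 = spec$pi0, seed = NULL) {
  stopifnot(inherits(spec, "scenario"))
  if (is.null(pi0)) stop("'pi0' must be given (the scenario draws it per dataset)")
  with_seed(seed, {
    theta <- numeric(m)
    alt_idx <- stats::runif(m) >= pi0
    n_alt <- sum(alt_idx)
    if (n_alt > 0) {
      comp <- sample.int(nrow(spec$alt), n_alt, replace = TRUE,
                         prob = spec$alt$weight)
      theta[alt_idx] <- stats::rnorm(n_alt, spec$alt$mean[comp], spec$alt$sd[comp])
    }
    theta
  })
}

#' Sample latent variances from a variance model
#'
#' @param model a [variance_model()].
#' @param m number of draws.
#' @param seed optional seed.
#' @return numeric vector of variances.
#' @export
sample_variances <- function(model, m, seed = NULL) {
  stopifnot(inherits(model, "variance_model"))
  with_seed(seed, switch(model$type,
    point_mass = rep(model$v, m),
    two_point = ifelse(stats::runif(m) < model$w, model$v1, model$v2),
    inverse_gamma = model$scale / stats::rgamma(m, shape = model$shape)
  ))
}

#' Simulate a complete two-group study from a scenario
#'
#' Draws latent effects and variances, then per-unit Gaussian samples:
#' group 1 `~ N(0, sigma2_i)` and group 2 `~ N(theta_i, sigma2_i)`,
#' `n_per_group` each, and reduces the matrix with [two_group_summary()]
#' (so `df = 2 * n_per_group - 2`). Fully determined by `seed`.
#'
#' @param spec a [scenario()].
#' @param seed integer seed (required).
#' @return An object of class `"twomix_sim"`: list with `theta`, `sigma2`,
#'   `pi0` (the value used; drawn from U(0.5, 1) when the scenario leaves it
#'   random), `gm` (the [grouped_matrix()]), `stats`
#'   (= `two_group_summary(gm)`), `spec`, `seed`.
#' @export
simulate_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario"))
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  with_seed(seed, {
    pi0 <- spec$pi0 %||% stats::runif(1, 0.5, 1)
    theta <- sample_effects(spec, pi0 = pi0)
    sigma2 <- sample_variances(spec$variance_model, spec$m)
    n <- spec$n_per_group
    sd_i <- sqrt(sigma2)
    y1 <- matrix(stats::rnorm(spec$m * n, 0, sd_i), spec$m, n)
    y2 <- matrix(stats::rnorm(spec$m * n, theta, sd_i), spec$m, n)
    gm <- grouped_matrix(cbind(y1, y2),
                         labels = rep(c("group1", "group2"), each = n))
    structure(
      list(theta = theta, sigma2 = sigma2, pi0 = pi0, gm = gm,
           stats = two_group_summary(gm), spec = spec, seed = seed),
      class = "twomix_sim"
    )
  })
}

#' @export
print.twomix_sim <- function(x, ...) {
  cat("Simulated study: scenario '", x$spec$name, "', m = ", x$spec$m,
      ", n/group = ", x$spec$n_per_group, ", pi0 = ", signif(x$pi0, 4),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' False discovery proportion of a list against known truth
#'
#' `FDP = #{i in list : theta_i = 0} / |list|`, defined as 0 for an empty
#' list.
#'
#' @param list a [discovery_list()] or an integer index vector.
#' @param theta true effects for all units.
#' @return scalar in `[0, 1]`.
#' @export
empirical_fdp <- function(list, theta) {
  idx <- if (inherits(list, "discovery_list")) list$indices else as.integer(list)
  if (length(idx) == 0) return(0)
  if (any(idx < 1 | idx > length(theta)))
    stop("'theta' must cover all listed units")
  mean(theta[idx] == 0)
}

#' 1-Wasserstein distance between two discrete distributions
#'
#' For distributions on finite real supports with equal total mass, the
#' distance is the integral of the absolute CDF difference: the sum over the
#' merged sorted support of `|CDF1 - CDF2| * gap` to the next point.
#'
#' @param x1,p1 support and masses of the first distribution.
#' @param x2,p2 support and masses of the second.
#' @return nonnegative scalar.
#' @export
#' @examples
#' wasserstein1(0, 1, 1, 1)                    # 1
#' wasserstein1(c(0, 1), c(.5, .5), 0, 1)      # 0.5
wasserstein1 <- function(x1, p1, x2, p2) {
  stopifnot(length(x1) == length(p1), length(x2) == length(p2),
            all(is.finite(c(x1, x2, p1, p2))))
  if (abs(sum(p1) - sum(p2)) > 1e-8)
    stop("total masses differ: ", sum(p1), " vs ", sum(p2))
  xs <- sort(unique(c(x1, x2)))
  m1 <- as.vector(rowsum(p1, match(x1, xs), reorder = TRUE))
  m2 <- as.vector(rowsum(p2, match(x2, xs), reorder = TRUE))
  full1 <- full2 <- numeric(length(xs))
  full1[sort(unique(match(x1, xs)))] <- m1
  full2[sort(unique(match(x2, xs)))] <- m2
  m1 <- full1; m2 <- full2
  cdf_diff <- abs(cumsum(m1) - cumsum(m2))
  if (length(xs) == 1L) return(0)
  sum(cdf_diff[-length(xs)] * diff(xs))
}

# Discretize a scenario's true effect mixing distribution (point null plus
# normal-mixture alternative) on a fine grid, for Wasserstein comparisons
# with a fitted g. Mass outside the grid is folded into the end bins.
discretize_true_g <- function(spec, pi0, n_grid = 2001) {
  sd_max <- max(abs(spec$alt$mean) + 6 * spec$alt$sd)
  grid <- seq(-sd_max, sd_max, length.out = n_grid)
  edges <- c(-Inf, (grid[-1] + grid[-n_grid]) / 2, Inf)
  cdf <- function(q) {
    out <- 0
    for (j in seq_len(nrow(spec$alt)))
      out <- out + spec$alt$weight[j] * stats::pnorm(q, spec$alt$mean[j], spec$alt$sd[j])
    out
  }
  mass_alt <- diff(cdf(edges))
  mass <- (1 - pi0) * mass_alt
  i0 <- which.min(abs(grid))
  grid[i0] <- 0  # make the null atom exact
  mass[i0] <- mass[i0] + pi0
  list(support = grid, mass = mass)
}

#' Operating characteristics of the two-mixture pipeline by simulation
#'
#' For each replicate: draw `pi0` (uniform on `[0.5, 1]` when the scenario
#' leaves it random), simulate a dataset, fit [twomix()], and record the
#' estimated null proportion, the 1-Wasserstein error of the fitted effect
#' mixing distribution against the generative one, and the false discovery
#' proportion and list size of the lfdr-threshold list at each nominal
#' level. Aggregates the empirical FDR (mean FDP) and mean `pi0`-hat within
#' four `pi0` strata: `[0.5, 0.625]`, `(0.625, 0.75]`, `(0.75, 0.875]`,
#' `(0.875, 1]`.
#'
#' @param specs a [scenario()] or a named list of scenarios.
#' @param reps replicates per scenario. Default 50.
#' @param nominal_levels lfdr thresholds. Default `c(0.05, 0.1)`.
#' @param seed master integer seed (required).
#' @param K,L grid sizes passed to [twomix()].
#' @param control optional [twomix_control()].
#' @return An object of class `"twomix_oc"`: list with `replicates` (one row
#'   per scenario x replicate: `pi0`, `pi0_hat`, `wasserstein`,
#'   `fdp_<level>`, `n_disc_<level>`, `failed`), `by_stratum` (empirical FDR
#'   and mean `pi0`-hat per scenario, stratum and level), `n_failed`,
#'   `levels`, `seed`.
#' @export
run_operating_characteristics <- function(specs, reps = 50,
                                          nominal_levels = c(0.05, 0.1),
                                          seed, K = 15, L = 20,
                                          control = twomix_control()) {
  if (inherits(specs, "scenario")) specs <- list(specs)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  stopifnot(reps >= 1, all(nominal_levels >= 0 & nominal_levels <= 1))
  if (missing(seed) || is.null(seed)) stop("'seed' is required")

  rows <- list()
  seeds <- matrix(derive_seeds(seed, reps * length(specs)),
                  nrow = reps)
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (r in seq_len(reps)) {
      sim <- simulate_dataset(spec, seed = seeds[r, si])
      row <- data.frame(scenario = names(specs)[si], rep = r,
                        pi0 = sim$pi0, pi0_hat = NA_real_,
                        wasserstein = NA_real_, failed = FALSE)
      res <- tryCatch({
        fit <- twomix(sim$stats, K = K, L = L, control = control)
        tg <- discretize_true_g(spec, sim$pi0)
        row$pi0_hat <- estimate_pi0(fit)
        row$wasserstein <- wasserstein1(fit$egrid$values, fit$g,
                                        tg$support, tg$mass)
        for (lev in nominal_levels) {
          dl <- discovery_list(fit, alpha = lev, statistic = "lfdr")
          row[[paste0("fdp_", lev)]] <- empirical_fdp(dl, sim$theta)
          row[[paste0("n_disc_", lev)]] <- dl$n
        }
        row
      }, error = function(e) {
        row$failed <- TRUE
        for (lev in nominal_levels) {
          row[[paste0("fdp_", lev)]] <- NA_real_
          row[[paste0("n_disc_", lev)]] <- NA_integer_
        }
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  replicates <- do.call(rbind, rows)

  brk <- c(0.5, 0.625, 0.75, 0.875, 1)
  ok <- !replicates$failed
  strat <- cut(replicates$pi0, breaks = brk, include.lowest = TRUE)
  agg <- list()
  for (sc in unique(replicates$scenario)) {
    for (st in levels(strat)) {
      sel <- ok & replicates$scenario == sc & strat == st
      if (!any(sel)) next
      for (lev in nominal_levels) {
        agg[[length(agg) + 1L]] <- data.frame(
          scenario = sc, stratum = st, level = lev,
          empirical_fdr = mean(replicates[[paste0("fdp_", lev)]][sel]),
          mean_pi0_hat = mean(replicates$pi0_hat[sel]),
          n_reps = sum(sel))
      }
    }
  }
  structure(
    list(replicates = replicates,
         by_stratum = if (length(agg)) do.call(rbind, agg) else NULL,
         n_failed = sum(replicates$failed),
         levels = nominal_levels, seed = seed),
    class = "twomix_oc"
  )
}

#' @export
print.twomix_oc <- function(x, ...) {
  cat("Operating characteristics over", nrow(x$replicates), "replicates (",
      x$n_failed, "failed )\n")
  ok <- !x$replicates$failed
  for (lev in x$levels)
    cat("  empirical FDR at", lev, ":",
        signif(mean(x$replicates[[paste0("fdp_", lev)]][ok]), 3), "\n")
  cat("  mean pi0-hat:", signif(mean(x$replicates$pi0_hat[ok]), 4),
      "(mean true pi0:", signif(mean(x$replicates$pi0[ok]), 4), ")\n")
  invisible(x)
}
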