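#' Double-log transform of raw intensities
#'
#' `log(log(y))` (natural logs), a variance-stabilizing transform for
#' fluorescence intensities from high-density arrays. Defined for `y > 1`.
#'
#' @param y raw intensities, all strictly greater than 1.
#' @return transformed values.
#' @export
#' @examples
#' double_log(exp(exp(1)))  # 1
double_log <- function(y) {
  if (any(!is.finite(y)) || any(y <= 1))
    stop("double_log is defined for finite y > 1")
  log(log(y))
}

#' Two-group intensity matrix
#'
#' Validated container for a units-by-samples matrix (already on the analysis
#' scale, e.g. after [double_log()]) with a two-group sample assignment. The
#' first factor level of `labels` is the reference group (group 1); the
#' second is the case group (group 2). Effects are reported as group 2 minus
#' group 1.
#'
#' @param values numeric matrix, units in rows, samples in columns.
#' @param labels per-sample group labels (coerced to factor; exactly two
#'   levels, each with at least 2 samples).
#' @return An object of class `"grouped_matrix"`: list with `values`,
#'   `labels`, `groups` (the two level names), `n1`, `n2`.
#' @export
grouped_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("'values' must be a finite numeric matrix")
  labels <- factor(labels)
  if (length(labels) != ncol(values))
    stop("'labels' must have one entry per sample (column)")
  if (nlevels(labels) != 2L) stop("exactly two groups are required")
  n <- table(labels)
  if (any(n < 2L)) stop("each group needs at least 2 samples")
  structure(
    list(values = values, labels = labels, groups = levels(labels),
         n1 = as.integer(n[1]), n2 = as.integer(n[2])),
    class = "grouped_matrix"
  )
}

#' Per-unit two-group summary statistics
#'
#' Reduces a two-group matrix to the model's data interface: per unit, the
#' effect `x_i = mean(group 2) - mean(group 1)`, the squared standard error
#' `s2_i = v_i * (1/n1 + 1/n2)` with pooled variance
#' `v_i = ((n1-1) var1 + (n2-1) var2) / (n1 + n2 - 2)` (sample variances with
#' divisor n-1), and the shared design degrees of freedom
#' `df = n1 + n2 - 2`.
#'
#' @param gm a [grouped_matrix()], or a numeric matrix (then `labels` is
#'   required).
#' @param labels per-sample group labels when `gm` is a plain matrix.
#' @param var_floor optional positive floor applied to the pooled variance.
#'   Off (`NULL`) by default: units with zero pooled variance are an error,
#'   never silently adjusted.
#' @return a [summary_stats()] object (unit ids from the matrix rownames when
#'   present).
#' @export
#' @examples
#' gm <- grouped_matrix(rbind(u1 = c(0, 2, 1, 3)), labels = c(1, 1, 2, 2))
#' ss <- two_group_summary(gm)  # x = 1, s2 = 2, df = 2
two_group_summary <- function(gm, labels = NULL, var_floor = NULL) {
  if (!inherits(gm, "grouped_matrix")) gm <- grouped_matrix(gm, labels)
  v <- gm$values
  i1 <- gm$labels == gm$groups[1]
  i2 <- gm$labels == gm$groups[2]
  n1 <- gm$n1; n2 <- gm$n2
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  var1 <- apply(v[, i1, drop = FALSE], 1, stats::var)
  var2 <- apply(v[, i2, drop = FALSE], 1, stats::var)
  pooled <- ((n1 - 1) * var1 + (n2 - 1) * var2) / (n1 + n2 - 2)
  if (!is.null(var_floor)) {
    stopifnot(var_floor > 0)
    pooled <- pmax(pooled, var_floor)
  } else if (any(pooled <= 0)) {
    bad <- which(pooled <= 0)
    ids <- rownames(v) %||% paste0("unit_", seq_len(nrow(v)))
    stop("zero pooled variance for unit(s): ",
         paste(utils::head(ids[bad], 10), collapse = ", "),
         " (consider 'var_floor')")
  }
  summary_stats(x = m2 - m1, s2 = pooled * (1 / n1 + 1 / n2),
                df = n1 + n2 - 2, unit_ids = rownames(v))
}

#' Permutation negative control for the discovery pipeline
#'
#' Fixes the data matrix and randomly shuffles the sample labels (preserving
#' group sizes), recomputes the two-group summaries, refits the two-mixture
#' model and thresholds the lfdr at `alpha`, recording the discovery-list
#' size for each permutation. Under label exchangeability the lists should be
#' (nearly always) empty.
#'
#' @param gm a [grouped_matrix()].
#' @param n_perm number of permutations (`>= 0`).
#' @param alpha lfdr threshold. Default 0.1.
#' @param K,L grid sizes passed to [twomix()].
#' @param seed integer seed (required): permutations are drawn from a
#'   dedicated stream so runs are reproducible.
#' @param control optional [twomix_control()].
#' @return An object of class `"twomix_permnull"`: list with `sizes` (integer
#'   vector of list sizes per permutation), `tab` (their tabulation),
#'   `alpha`, `n_perm`, `seed`.
#' @export
permutation_null <- function(gm, n_perm, alpha = 0.1, K = 15, L = 20,
                             seed, control = twomix_control()) {
  stopifnot(inherits(gm, "grouped_matrix"), n_perm >= 0)
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  sizes <- integer(0)
  if (n_perm > 0) {
    seeds <- derive_seeds(seed, n_perm)
    sizes <- vapply(seq_len(n_perm), function(p) {
      labs <- with_seed(seeds[p], sample(gm$labels))
      pgm <- grouped_matrix(gm$values, labs)
      fit <- twomix(two_group_summary(pgm), K = K, L = L, control = control)
      discovery_list(fit, alpha = alpha, statistic = "lfdr")$n
    }, integer(1))
  }
  structure(
    list(sizes = sizes, tab = table(sizes), alpha = alpha,
         n_perm = as.integer(n_perm), seed = seed),
    class = "twomix_permnull"
  )
}

#' @export
print.twomix_permnull <- function(x, ...) {
  cat("Permutation negative control:", x$n_perm, "label shuffles, lfdr <=",
      x$alpha, "\n")
  if (x$n_perm > 0) {
    cat("  empty lists:", sum(x$sizes == 0), "/", x$n_perm, "\n")
    cat("  list-size tabulation:\n")
    print(x$tab)
  }
  invisible(x)
}
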