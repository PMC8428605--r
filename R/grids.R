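#' Per-unit summary statistics for the two-mixture model
#'
#' Container for the method's entire data interface: one estimated effect
#' `x_i` and one squared standard error `s2_i` per testing unit, plus a single
#' design-based degrees of freedom `df` shared by all units (in the classical
#' two-group comparison, total samples minus two).
#'
#' @param x numeric vector of estimated effects (e.g. difference of group
#'   means of double-log intensities).
#' @param s2 numeric vector of squared standard errors, strictly positive.
#'   Exactly one of `s2` and `s` must be given.
#' @param df scalar degrees of freedom, `>= 1`. A vector of per-unit degrees
#'   of freedom is rejected: the scaled chi-square sampling model assumes a
#'   shared, design-determined value.
#' @param s numeric vector of standard errors; squared on ingest.
#' @param unit_ids optional character labels, defaulting to `"unit_1"`, ...
#'
#' @return An object of class `"summary_stats"`: a list with elements
#'   `unit_ids`, `x`, `s2`, `df` and `m` (number of units).
#' @seealso [two_group_summary()] to compute these from a raw intensity
#'   matrix; [twomix()] to fit the model.
#' @export
#' @examples
#' ss <- summary_stats(x = c(0.1, -0.3), s2 = c(0.5, 0.7), df = 18)
#' ss$m
summary_stats <- function(x, s2 = NULL, df, s = NULL, unit_ids = NULL) {
  if (!is.null(s) && !is.null(s2))
    stop("supply exactly one of 's' and 's2', not both")
  if (is.null(s2)) {
    if (is.null(s)) stop("one of 's' and 's2' is required")
    s2 <- as.numeric(s)^2
  }
  x <- as.numeric(x)
  s2 <- as.numeric(s2)
  if (length(x) < 1L) stop("'x' must be nonempty")
  if (length(x) != length(s2))
    stop("'x' and 's2' must have equal length")
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (!all(is.finite(s2)) || any(s2 <= 0))
    stop("'s2' must be finite and strictly positive; offending rows: ",
         paste(utils::head(which(!is.finite(s2) | s2 <= 0), 10), collapse = ", "))
  if (length(df) != 1L)
    stop("'df' must be a single shared value (per-unit degrees of freedom are not supported)")
  df <- as.numeric(df)
  if (!is.finite(df) || df < 1) stop("'df' must be a finite number >= 1")
  if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_along(x))
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) != length(x))
    stop("'unit_ids' must match the number of units")
  structure(
    list(unit_ids = unit_ids, x = x, s2 = s2, df = df, m = length(x)),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("Summary statistics for", x$m, "units (df =", x$df, ")\n")
  cat("  x : ", paste(signif(range(x$x), 4), collapse = " .. "), "\n")
  cat("  s2: ", paste(signif(range(x$s2), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Regular effect grid carrying the unimodal mixing distribution
#'
#' Builds the support `a_{-K}, ..., a_0, ..., a_K` of the effect mixing
#' distribution: `2K + 1` equally spaced points, symmetric about the presumed
#' mode `a_0` (0 in applications that retain a point null), with half-width
#' equal to the largest absolute deviation of the effect estimates from the
#' mode, so every estimate lies inside the grid.
#'
#' @param x numeric vector of effect estimates used to set the half-width.
#' @param K half-number of grid points; the grid has `2K + 1` points.
#'   Default 15.
#' @param mode location of the grid mode `a_0` (default 0).
#'
#' @return An object of class `"effect_grid"`: list with `values`, `K`,
#'   `mode_value`, `spacing` and `mode_index` (position of `a_0`).
#' @export
#' @examples
#' effect_grid(c(-3, 1, 2), K = 2)$values  # -3 -1.5 0 1.5 3
effect_grid <- function(x, K = 15, mode = 0) {
  x <- as.numeric(x)
  if (length(x) < 1L || !all(is.finite(x))) stop("'x' must be nonempty and finite")
  if (length(K) != 1L || K < 1 || K != round(K)) stop("'K' must be a positive integer")
  K <- as.integer(K)
  if (!is.finite(mode) || length(mode) != 1L) stop("'mode' must be a finite scalar")
  half_width <- max(abs(x - mode))
  if (half_width <= 0)
    stop("degenerate input: all effect estimates equal the mode; ",
         "the effect grid would have zero half-width")
  values <- mode + seq(-half_width, half_width, length.out = 2L * K + 1L)
  values[K + 1L] <- mode  # exact, not up to rounding
  structure(
    list(values = values, K = K, mode_value = mode,
         spacing = half_width / K, mode_index = K + 1L),
    class = "effect_grid"
  )
}

#' Regular variance grid carrying the free mixing distribution
#'
#' Builds the support `b_1 < ... < b_L` of the variance mixing distribution:
#' `L` equally spaced points spanning the observed range of squared standard
#' errors. When all `s2` are equal the span is padded to +/- 5% of the common
#' value; when `L = 1` the single point is the span midpoint.
#'
#' @param s2 numeric vector of squared standard errors, strictly positive.
#' @param L number of grid points. Default 20, matching [twomix()].
#'
#' @return An object of class `"variance_grid"`: list with `values` and `L`.
#' @export
#' @examples
#' variance_grid(c(1, 2, 5), L = 3)$values  # 1 3 5
variance_grid <- function(s2, L = 20) {
  s2 <- as.numeric(s2)
  if (length(s2) < 1L || !all(is.finite(s2)) || any(s2 <= 0))
    stop("'s2' must be nonempty, finite and strictly positive")
  if (length(L) != 1L || L < 1 || L != round(L)) stop("'L' must be a positive integer")
  L <- as.integer(L)
  lo <- min(s2); hi <- max(s2)
  if (lo == hi) { lo <- 0.95 * lo; hi <- 1.05 * hi }
  values <- if (L == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = L)
  structure(list(values = values, L = L), class = "variance_grid")
}

#' @export
print.effect_grid <- function(x, ...) {
  cat("Effect grid: 2K+1 =", 2L * x$K + 1L, "points on [",
      signif(min(x$values), 4), ",", signif(max(x$values), 4),
      "], mode", x$mode_value, "\n")
  invisible(x)
}

#' @export
print.variance_grid <- function(x, ...) {
  cat("Variance grid:", x$L, "points on [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}
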