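# Detect the delimiter of a header line: tab if present, else comma.
detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0L) stop("empty file: ", path)
  if (grepl("\t", line)) "\t" else ","
}

#' Read per-unit summary statistics from a delimited table
#'
#' Reads a TSV or CSV file (delimiter auto-detected; header required) and
#' returns validated [summary_stats()]. Exactly one of a squared-standard-
#' error column (`s2`) or a standard-error column (`s`, squared on ingest)
#' must be mapped.
#'
#' @param path file path.
#' @param df shared degrees of freedom (required; not stored in the table).
#' @param id,x,s2,s column names; set `s2 = NULL` and `s = "s"` to ingest
#'   standard errors instead of their squares. An `id` column is optional:
#'   if absent, row numbers are used.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return a [summary_stats()] object.
#' @export
read_summary_table <- function(path, df, id = "id", x = "x", s2 = "s2",
                               s = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(s) && !is.null(s2)) stop("map exactly one of 's' and 's2'")
  if (is.null(s) && is.null(s2)) stop("one of 's' and 's2' must be mapped")
  sep <- sep %||% detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(x, s2, s)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  if (anyNA(tab[, need]))
    stop("missing values in mapped columns (rows ",
         paste(utils::head(which(rowSums(is.na(tab[, need, drop = FALSE])) > 0), 10),
               collapse = ", "), "); missing data are rejected, not imputed")
  ids <- if (!is.null(id) && id %in% names(tab)) as.character(tab[[id]]) else NULL
  sv <- if (!is.null(s2)) tab[[s2]] else tab[[s]]^2
  bad <- which(!is.finite(sv) | sv <= 0)
  if (length(bad))
    stop("nonpositive standard error values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  summary_stats(x = tab[[x]], s2 = sv, df = df, unit_ids = ids)
}

# Full-precision serialization helper (round-trip safe doubles).
fmt_num <- function(v) formatC(v, digits = 17, format = "g")

#' Write fit results to delimited files
#'
#' Writes the per-unit results table (`id`, `x`, `s2`, `lfdr`, `lfsr`,
#' `significant` at the configured level) to `path`, and a side file
#' (`<path>.mixing.tsv`) recording the estimated mixing distributions with
#' their grid values plus the attained log-likelihood, estimated null
#' proportion and convergence status. All numbers are serialized at 17
#' significant digits so a read-back is bit-faithful.
#'
#' @param fit a `"twomix"` object.
#' @param path output path for the main table (tab-delimited).
#' @param alpha threshold defining the `significant` column. Default 0.1.
#' @param statistic `"lfdr"` (default) or `"lfsr"`.
#' @return invisibly, the two paths written.
#' @export
write_results <- function(fit, path, alpha = 0.1,
                          statistic = c("lfdr", "lfsr")) {
  stopifnot(inherits(fit, "twomix"))
  statistic <- match.arg(statistic)
  post <- fit$posterior
  dl <- discovery_list(post, alpha = alpha, statistic = statistic)
  main <- data.frame(
    id = fit$stats$unit_ids,
    x = fmt_num(fit$stats$x),
    s2 = fmt_num(fit$stats$s2),
    lfdr = fmt_num(post$lfdr),
    lfsr = fmt_num(post$lfsr),
    significant = as.integer(seq_len(fit$stats$m) %in% dl$indices)
  )
  tryCatch(
    utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write results to '", path, "': ",
                             conditionMessage(e)))
  side_path <- paste0(path, ".mixing.tsv")
  side <- data.frame(
    component = c(rep("g", length(fit$g)), rep("h", length(fit$h))),
    grid_value = fmt_num(c(fit$egrid$values, fit$vgrid$values)),
    mass = fmt_num(c(fit$g, fit$h))
  )
  con <- file(side_path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# loglik=", fmt_num(fit$loglik)),
               paste0("# pi0_hat=", fmt_num(fit$pi0)),
               paste0("# converged=", fit$converged),
               paste0("# df=", fmt_num(fit$stats$df))), con)
  utils::write.table(side, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, side_path))
}

#' Read a run configuration from YAML
#'
#' A YAML file may mirror any of the command-line flags (e.g. `input`, `df`,
#' `K`, `L`, `mode`, `fdr`, `statistic`, `subsample`, `seed`, `output`,
#' column mappings `id_col`, `x_col`, `s_col`, `s2_col`). Command-line flags
#' take precedence over the file.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
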