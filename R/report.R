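# recursively sort names so JSON output is key-stable
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x), method = "radix")]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else x
}

#' Write a statistics table as deterministic TSV
#'
#' Numeric columns are formatted with 6 significant digits; rows are
#' written in input order; the same input always yields byte-identical
#' output. An empty data.frame produces a header-only file.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_stats_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write model metrics as deterministic JSON
#'
#' Keys are sorted recursively; scalars are unboxed; the same input
#' always yields byte-identical output.
#'
#' @param metrics named list of metrics (may be nested).
#' @param path output path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(sort_keys(metrics), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-ratio statistics and model metrics
#'
#' Convenience writer for a pipeline stage: a TSV for the per-ratio
#' statistics table and a JSON file for the model metrics, both
#' deterministic.
#'
#' @param results list with elements `stats` (data.frame, optional) and
#'   `metrics` (named list, optional).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return character vector of written paths.
#' @export
write_report <- function(results, dir, prefix = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(results$stats)) {
    p <- file.path(dir, paste0(prefix, "_stats.tsv"))
    write_stats_tsv(results$stats, p)
    paths <- c(paths, p)
  }
  if (!is.null(results$metrics)) {
    p <- file.path(dir, paste0(prefix, "_metrics.json"))
    write_metrics_json(results$metrics, p)
    paths <- c(paths, p)
  }
  paths
}
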