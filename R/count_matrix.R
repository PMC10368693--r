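#' Construct a validated miR count matrix
#'
#' The sequencing-side input of the pipeline: raw miR counts (no
#' normalization — downstream features are within-sample ratios, so
#' per-sample scaling cancels) together with the case/control label of
#' every sample.
#'
#' @param counts non-negative integer matrix, miRs in rows (unique
#'   rownames), samples in columns (unique colnames).
#' @param labels character vector of "case"/"control", either named by
#'   sample id or in column order.
#' @return an object of class `count_matrix`: a list with `mir_ids`,
#'   `sample_ids`, `counts` and `labels` (named character vector).
#' @export
count_matrix <- function(counts, labels) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have miR rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated miR ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numeric")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative count at miR '", rownames(counts)[neg[1, 1]],
         "', sample '", colnames(counts)[neg[1, 2]], "'")
  sids <- colnames(counts)
  if (!is.null(names(labels))) {
    unknown <- setdiff(names(labels), sids)
    if (length(unknown) > 0)
      stop("labels refer to unknown samples: ", paste(unknown, collapse = ", "))
    missing <- setdiff(sids, names(labels))
    if (length(missing) > 0)
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    labels <- labels[sids]
  } else {
    if (length(labels) != ncol(counts))
      stop("labels length (", length(labels), ") != number of samples (",
           ncol(counts), ")")
    names(labels) <- sids
  }
  label01(labels) # validates values
  structure(
    list(mir_ids = rownames(counts), sample_ids = sids,
         counts = counts, labels = labels),
    class = "count_matrix"
  )
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$mir_ids), "miRs x", length(x$sample_ids),
      "samples (", sum(x$labels == "case"), "cases /",
      sum(x$labels == "control"), "controls )\n")
  invisible(x)
}

#' Read a miR count matrix and sample labels from TSV files
#'
#' @param path TSV with a header row; first column miR ids, remaining
#'   columns one per sample, integer raw counts.
#' @param label_path TSV with columns `sample_id` and `label`
#'   ("case"/"control"); must cover exactly the samples in `path`.
#' @return a validated [count_matrix()].
#' @export
read_count_matrix <- function(path, label_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file needs a miR id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated miR ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  lab <- utils::read.delim(label_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(lab)))
    stop("label file must have columns sample_id, label")
  labels <- stats::setNames(as.character(lab$label), as.character(lab$sample_id))
  count_matrix(m, labels)
}

#' Write a count matrix (and its labels) to TSV files
#'
#' Inverse of [read_count_matrix()]; `read(write(x))` round-trips.
#'
#' @param cm a `count_matrix`.
#' @param path,label_path output TSV paths.
#' @export
write_count_matrix <- function(cm, path, label_path) {
  df <- data.frame(mir_id = cm$mir_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = cm$sample_ids, label = unname(cm$labels))
  utils::write.table(lab, label_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, label_path))
}
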