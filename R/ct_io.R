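#' Read a long-format RT-qPCR Ct table
#'
#' One row per replicate: columns `sample_id`, `assay_id`, `replicate`,
#' `ct`. `ct` is a Ct value in (0, 45\] or the literal `"ND"` for a
#' non-detect (stored as `NA`). Each (sample, assay) pair must have 1-3
#' replicate rows. QC is *not* applied here — see [qc_ct_plates()].
#'
#' @param path TSV path.
#' @return data.frame with `ct` numeric (`NA` = non-detect) and logical
#'   `nondetect`.
#' @export
read_ct_plates <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "assay_id", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct file must have columns: ", paste(need, collapse = ", "))
  nd <- toupper(trimws(df$ct)) == "ND"
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(!nd & (is.na(ct) | ct <= 0 | ct > 45))
  if (length(bad) > 0)
    stop("invalid Ct at row ", bad[1], ": '", df$ct[bad[1]],
         "' (must be in (0, 45] or \"ND\")")
  ct[nd] <- NA_real_
  out <- data.frame(sample_id = df$sample_id, assay_id = df$assay_id,
                    replicate = as.integer(df$replicate), ct = ct,
                    nondetect = nd, stringsAsFactors = FALSE)
  nrep <- table(interaction(out$sample_id, out$assay_id, drop = TRUE))
  if (any(nrep > 3)) {
    off <- names(nrep)[which(nrep > 3)[1]]
    stop("more than 3 replicates for (sample, assay) ", off)
  }
  out
}

#' Write a long-format Ct table
#'
#' Inverse of [read_ct_plates()]; non-detects are written as `"ND"`.
#'
#' @param plates data.frame with `sample_id`, `assay_id`, `replicate`,
#'   `ct` (`NA` = non-detect).
#' @param path output TSV path.
#' @export
write_ct_plates <- function(plates, path) {
  ct <- ifelse(is.na(plates$ct), "ND", fmt_num(plates$ct))
  out <- data.frame(sample_id = plates$sample_id,
                    assay_id = plates$assay_id,
                    replicate = plates$replicate, ct = ct)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
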