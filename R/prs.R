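#' Read a SNP weight panel
#'
#' @param path TSV with columns `snp_id` and `log_or`.
#' @return named numeric vector of per-SNP log odds ratios.
#' @export
read_panel_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "log_or") %in% names(df)))
    stop("weights file must have columns snp_id, log_or")
  if (anyDuplicated(df$snp_id))
    stop("duplicated snp ids: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  w <- as.numeric(df$log_or)
  if (any(!is.finite(w))) stop("non-finite weight for snp ",
                               df$snp_id[which(!is.finite(w))[1]])
  stats::setNames(w, df$snp_id)
}

#' Polygenic risk score from genotype dosages
#'
#' PRS = sum over SNPs of (per-SNP log odds ratio) x (risk-allele
#' dosage, 0 for wildtype, 1 heterozygous, 2 homozygous variant).
#' Missing dosages contribute zero by default and are counted; optional
#' mean-dosage imputation (`2 * allele frequency`) is available.
#'
#' @param dosages matrix or data.frame (samples x SNPs) with values in
#'   {0, 1, 2} or `NA`; column names are snp ids.
#' @param weights named numeric vector of log odds ratios covering every
#'   SNP column.
#' @param impute_af optional named vector of risk-allele frequencies;
#'   when given, missing dosages are imputed as `2 * af` instead of 0.
#' @return data.frame with `sample_id`, `prs`, `n_missing`.
#' @export
compute_prs <- function(dosages, weights, impute_af = NULL) {
  m <- as.matrix(dosages)
  if (is.null(colnames(m))) stop("dosage columns must be named by snp id")
  bad <- !(m %in% c(0, 1, 2) | is.na(m))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    stop("dosage outside {0,1,2} at sample ",
         (rownames(m) %||% seq_len(nrow(m)))[idx[1]], ", snp ",
         colnames(m)[idx[2]])
  }
  noweight <- setdiff(colnames(m), names(weights))
  if (length(noweight) > 0)
    stop("no weight for snp(s): ", paste(noweight, collapse = ", "))
  w <- weights[colnames(m)]
  n_missing <- rowSums(is.na(m))
  if (is.null(impute_af)) {
    m[is.na(m)] <- 0
  } else {
    af <- impute_af[colnames(m)]
    if (any(is.na(af))) stop("impute_af must cover every snp column")
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- 2 * af[j]
  }
  data.frame(sample_id = rownames(m) %||% as.character(seq_len(nrow(m))),
             prs = drop(m %*% w), n_missing = n_missing,
             row.names = NULL, stringsAsFactors = FALSE)
}
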