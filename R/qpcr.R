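#' Triplicate Ct quality control
#'
#' Single pass, in the stated order: (1) non-detects are replaced with
#' Ct 40; (2) mean and sample standard deviation are computed; (3) any
#' replicate lying strictly more than one standard deviation from the
#' mean is excluded (for a triplicate at most one replicate can qualify,
#' since the squared deviations sum to exactly twice the sample
#' variance); (4) the mean is recomputed from the survivors. No
#' iteration. Duplicates (2 replicates) skip the outlier rule — with two
#' points each deviation equals the sd, so the rule would always fire —
#' and are flagged. A boundary replicate exactly one sd from the mean is
#' retained (comparison uses a 1e-9 tolerance against floating-point
#' noise).
#'
#' @param cts numeric vector of 1-3 replicate Ct values; `NA` marks a
#'   non-detect.
#' @param nondetect_ct imputed Ct for non-detects (default 40).
#' @return list with `ct_mean`, `excluded` (integer indices of removed
#'   replicates), `nondetect` (indices imputed), `all_nondetect`
#'   (logical flag), `doublet` (logical flag).
#' @export
qc_triplicate <- function(cts, nondetect_ct = 40) {
  if (length(cts) < 1 || length(cts) > 3)
    stop("expected 1-3 replicates, got ", length(cts))
  nd <- which(is.na(cts))
  cts[nd] <- nondetect_ct
  all_nd <- length(nd) == length(cts)
  if (length(cts) == 1) {
    return(list(ct_mean = cts, excluded = integer(0), nondetect = nd,
                all_nondetect = all_nd, doublet = FALSE))
  }
  if (length(cts) == 2) {
    return(list(ct_mean = mean(cts), excluded = integer(0), nondetect = nd,
                all_nondetect = all_nd, doublet = TRUE))
  }
  m <- mean(cts)
  s <- stats::sd(cts)
  excl <- which(abs(cts - m) - s > 1e-9)
  ct_mean <- if (length(excl) > 0) mean(cts[-excl]) else m
  list(ct_mean = ct_mean, excluded = excl, nondetect = nd,
       all_nondetect = all_nd, doublet = FALSE)
}

#' Apply triplicate QC to a long-format Ct table
#'
#' @param plates data.frame from [read_ct_plates()] (columns
#'   `sample_id`, `assay_id`, `replicate`, `ct` with `NA` non-detects).
#' @param nondetect_ct imputed Ct for non-detects (default 40).
#' @return data.frame with one row per (sample, assay): `sample_id`,
#'   `assay_id`, `ct_mean`, `n_replicates`, `n_excluded`,
#'   `n_nondetect`, `all_nondetect`, `doublet`.
#' @export
qc_ct_plates <- function(plates, nondetect_ct = 40) {
  key <- interaction(plates$sample_id, plates$assay_id, drop = TRUE)
  parts <- split(plates, key)
  rows <- lapply(parts, function(d) {
    q <- qc_triplicate(d$ct, nondetect_ct)
    data.frame(sample_id = d$sample_id[1], assay_id = d$assay_id[1],
               ct_mean = q$ct_mean, n_replicates = nrow(d),
               n_excluded = length(q$excluded),
               n_nondetect = length(q$nondetect),
               all_nondetect = q$all_nondetect, doublet = q$doublet,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$assay_id, method = "radix"), , drop = FALSE]
}

#' Delta-Ct ratio of two assays
#'
#' `Ct_mean(Y) - Ct_mean(X)` for the ratio X/Y: since Ct falls by one
#' cycle per doubling of template, this approximates the log2 abundance
#' ratio of X over Y. Antisymmetric under swapping the arguments.
#'
#' @param ct_mean_x,ct_mean_y QC'd mean Ct of numerator and denominator
#'   assays.
#' @return numeric delta-Ct value(s).
#' @export
delta_ct_ratio <- function(ct_mean_x, ct_mean_y) {
  ct_mean_y - ct_mean_x
}

#' Per-sample delta-Ct ratio matrix
#'
#' @param ct_means data.frame from [qc_ct_plates()].
#' @param ratios data.frame with columns `numerator`, `denominator`
#'   (assay ids), e.g. from [map_sequencing_ratios_to_assays()].
#' @return matrix (ratios x samples) of delta-Ct values, rownames
#'   `"<numerator>_<denominator>"`.
#' @export
delta_ct_matrix <- function(ct_means, ratios) {
  samples <- lex_sort(unique(ct_means$sample_id))
  wide <- matrix(NA_real_, nrow = length(unique(ct_means$assay_id)),
                 ncol = length(samples),
                 dimnames = list(lex_sort(unique(ct_means$assay_id)), samples))
  wide[cbind(ct_means$assay_id, ct_means$sample_id)] <- ct_means$ct_mean
  miss <- setdiff(unique(c(ratios$numerator, ratios$denominator)),
                  rownames(wide))
  if (length(miss) > 0)
    stop("no Ct data for assay(s): ", paste(miss, collapse = ", "))
  out <- wide[ratios$denominator, , drop = FALSE] -
    wide[ratios$numerator, , drop = FALSE]
  rownames(out) <- paste(ratios$numerator, ratios$denominator, sep = "_")
  out
}

# strip a trailing locus suffix ("-1", "-2", ...) from a mature-miR arm
# id such as "let-7f-5p-2"; ids without an arm suffix are left alone
collapse_locus <- function(id) {
  sub("^((?:.*-)?(?:3p|5p))-[0-9]+$", "\\1", id)
}

#' Map sequencing-stage ratios to qPCR assay ratios
#'
#' Sequencing keeps same-name miRs from different genomic loci separate
#' (locus-suffixed ids such as `let-7f-5p-1` / `let-7f-5p-2`); their
#' mature sequences are identical, so at the qPCR stage each collapses
#' to one mature-miR assay. Merged dedup ids (`"a|b"`) are resolved to
#' a single mature id when all constituents collapse to the same one.
#' Ratios identical after collapse are reported once; an explicit
#' manual-exclusion list is applied last.
#'
#' @param ratio_ids character vector of sequencing ratio ids
#'   (`"<numerator>_<denominator>"`).
#' @param exclusions assay-level ratio ids to drop (after collapse and
#'   canonicalisation).
#' @return list with `ratios` (data.frame `numerator`, `denominator`,
#'   `ratio_id`, `source_ids`), and `mirs` (unique mature miR ids the
#'   assays require).
#' @export
map_sequencing_ratios_to_assays <- function(ratio_ids,
                                            exclusions = character(0)) {
  collapse_one <- function(id) {
    members <- strsplit(id, "|", fixed = TRUE)[[1]]
    mm <- unique(collapse_locus(members))
    if (length(mm) > 1) {
      warning("merged id '", id, "' maps to several mature miRs; using ",
              mm[1])
    }
    mm[1]
  }
  parts <- strsplit(ratio_ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("unmappable ratio id(s): ", paste(ratio_ids[bad], collapse = ", "))
  num <- vapply(parts, function(p) collapse_one(p[1]), character(1))
  den <- vapply(parts, function(p) collapse_one(p[2]), character(1))
  degenerate <- num == den
  if (any(degenerate)) {
    warning("ratio(s) degenerate after locus collapse, dropped: ",
            paste(ratio_ids[degenerate], collapse = ", "))
    num <- num[!degenerate]; den <- den[!degenerate]
    ratio_ids <- ratio_ids[!degenerate]
  }
  swap <- den < num
  tmp <- num[swap]; num[swap] <- den[swap]; den[swap] <- tmp
  rid <- paste(num, den, sep = "_")
  src <- vapply(split(ratio_ids, rid), paste, character(1), collapse = ";")
  keep <- !duplicated(rid)
  df <- data.frame(numerator = num[keep], denominator = den[keep],
                   ratio_id = rid[keep], stringsAsFactors = FALSE)
  df$source_ids <- unname(src[df$ratio_id])
  df <- df[!(df$ratio_id %in% exclusions), , drop = FALSE]
  df <- df[order(df$ratio_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  list(ratios = df, mirs = lex_sort(unique(c(df$numerator, df$denominator))))
}

#' Cross-platform concordance of ratio measurements
#'
#' Spearman rank correlation per ratio between the sequencing values
#' (log2 scale for interpretability; Spearman is invariant to the
#' monotone transform) and the delta-Ct values on the same samples. A
#' ratio is flagged concordant when p < `alpha` and rho > 0.
#'
#' @param seq_log_ratios,dct_ratios matrices (ratios x samples) with
#'   matching rownames; columns are matched by sample id.
#' @param alpha significance gate for the concordant flag (default
#'   0.01).
#' @return data.frame with `ratio_id`, `rho`, `p`, `concordant`, `n`.
#' @export
cross_platform_concordance <- function(seq_log_ratios, dct_ratios,
                                       alpha = 0.01) {
  common_r <- intersect(rownames(seq_log_ratios), rownames(dct_ratios))
  common_s <- intersect(colnames(seq_log_ratios), colnames(dct_ratios))
  if (length(common_s) < 3) stop("need >= 3 paired samples, got ",
                                 length(common_s))
  if (length(common_r) == 0) stop("no shared ratio ids between platforms")
  rows <- lapply(common_r, function(r) {
    a <- seq_log_ratios[r, common_s]
    b <- dct_ratios[r, common_s]
    ok <- !is.na(a) & !is.na(b)
    ct <- suppressWarnings(
      stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE)
    )
    data.frame(ratio_id = r, rho = unname(ct$estimate), p = ct$p.value,
               concordant = ct$p.value < alpha && ct$estimate > 0,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Association of a ratio with a covariate
#'
#' Dispatches on the covariate type exactly as the analysis plan
#' prescribes: Mann-Whitney for a two-level covariate, Kruskal-Wallis
#' for more levels, Spearman correlation for a continuous covariate.
#'
#' @param values numeric ratio values per sample.
#' @param covariate covariate vector (same length).
#' @param type `"auto"` (factor/character or <= 2 distinct numeric
#'   values -> categorical; otherwise continuous), `"categorical"` or
#'   `"continuous"`.
#' @return list with `test` ("mann-whitney", "kruskal-wallis" or
#'   "spearman"), `p`, and `statistic` (U, KW chi-square, or rho).
#' @export
ratio_covariate_association <- function(values, covariate,
                                        type = c("auto", "categorical",
                                                 "continuous")) {
  type <- match.arg(type)
  keep <- !is.na(values) & !is.na(covariate)
  values <- values[keep]; covariate <- covariate[keep]
  if (type == "auto") {
    type <- if (is.character(covariate) || is.factor(covariate) ||
                length(unique(covariate)) <= 2) "categorical" else "continuous"
  }
  if (type == "categorical") {
    f <- factor(covariate)
    if (nlevels(f) < 2) stop("covariate has a single level")
    if (nlevels(f) == 2) {
      mw <- mann_whitney(values[f == levels(f)[1]], values[f == levels(f)[2]])
      return(list(test = "mann-whitney", p = mw$p, statistic = mw$U))
    }
    kw <- stats::kruskal.test(values, f)
    return(list(test = "kruskal-wallis", p = kw$p.value,
                statistic = unname(kw$statistic)))
  }
  ct <- suppressWarnings(
    stats::cor.test(values, covariate, method = "spearman", exact = FALSE)
  )
  list(test = "spearman", p = ct$p.value, statistic = unname(ct$estimate))
}
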