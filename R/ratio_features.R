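#' Filter miRs by mean raw count
#'
#' Retains exactly the miRs whose across-sample mean raw count is
#' strictly greater than `min_mean` (default 20). The sample set is
#' unchanged.
#'
#' @param cm a [count_matrix()].
#' @param min_mean retention threshold on the across-sample mean count;
#'   the comparison is strict (`mean > min_mean`).
#' @return the filtered `count_matrix`.
#' @export
filter_mirs <- function(cm, min_mean = 20) {
  keep <- rowMeans(cm$counts) > min_mean
  if (!any(keep)) stop("no miRs retained at min_mean = ", min_mean)
  count_matrix(cm$counts[keep, , drop = FALSE], cm$labels)
}

#' Collapse miRs with identical count profiles
#'
#' miRs whose count vectors are identical across all samples (clustered
#' loci, or one mature miR carried under two names) are collapsed to a
#' single row under a merged identifier `"id1|id2"`; the alias map from
#' each removed id to its retained representative is returned.
#'
#' @param cm a `count_matrix`.
#' @param tolerance maximum absolute per-sample difference for two
#'   profiles to be treated as identical. Default 0: exact equality.
#' @return list with `cm` (deduplicated `count_matrix`) and `map`
#'   (named character vector, removed id -> merged representative id;
#'   empty when all rows are distinct).
#' @export
deduplicate_profiles <- function(cm, tolerance = 0) {
  m <- cm$counts
  n <- nrow(m)
  group <- seq_len(n)
  if (tolerance == 0) {
    key <- apply(m, 1, paste, collapse = "\r")
    group <- match(key, key)
  } else {
    for (i in seq_len(n)[-1]) {
      for (j in seq_len(i - 1)) {
        if (group[j] == j && max(abs(m[i, ] - m[j, ])) <= tolerance) {
          group[i] <- j
          break
        }
      }
    }
  }
  if (all(group == seq_len(n))) {
    return(list(cm = cm, map = stats::setNames(character(0), character(0))))
  }
  reps <- unique(group)
  ids <- rownames(m)
  merged_id <- vapply(reps, function(g) {
    paste(ids[group == g], collapse = "|")
  }, character(1))
  out <- m[reps, , drop = FALSE]
  rownames(out) <- merged_id
  removed <- ids[group != seq_len(n)]
  map <- stats::setNames(merged_id[match(group[group != seq_len(n)], reps)],
                         removed)
  list(cm = count_matrix(out, cm$labels), map = map)
}

canonical_ratio_id <- function(a, b) {
  swap <- b < a
  num <- ifelse(swap, b, a)
  den <- ifelse(swap, a, b)
  paste(num, den, sep = "_")
}

#' Build the all-pairs ratio matrix
#'
#' One ratio per unordered pair of retained miRs: for `n` miRs, exactly
#' `n(n-1)/2` ratios. Orientation is canonical — the lexicographically
#' smaller miR id is the numerator — so the construction is
#' deterministic and reversible (flipping a pair inverts the value
#' pointwise). A pseudocount is added to numerator and denominator so
#' ratios stay finite when a raw count is zero; on zero-free data it
#' leaves within-ratio sample ranks unchanged.
#'
#' @param cm a deduplicated `count_matrix` with at least 2 miRs.
#' @param pseudocount added to both counts before division (default 1).
#' @return object of class `ratio_matrix`: list with `pairs`
#'   (data.frame `numerator`, `denominator`, `ratio_id`), `values`
#'   (positive matrix, ratios x samples), `sample_ids`, `labels`.
#' @export
build_ratio_matrix <- function(cm, pseudocount = 1) {
  ids <- lex_sort(cm$mir_ids)
  n <- length(ids)
  if (n < 2) stop("need at least 2 miRs to form ratios, got ", n)
  pr <- utils::combn(ids, 2)
  num <- pr[1, ]
  den <- pr[2, ]
  values <- (cm$counts[num, , drop = FALSE] + pseudocount) /
    (cm$counts[den, , drop = FALSE] + pseudocount)
  rid <- paste(num, den, sep = "_")
  rownames(values) <- rid
  structure(
    list(pairs = data.frame(numerator = num, denominator = den,
                            ratio_id = rid, stringsAsFactors = FALSE),
         values = values,
         sample_ids = cm$sample_ids,
         labels = cm$labels),
    class = "ratio_matrix"
  )
}

#' @exportS3Method base::print
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", nrow(x$values), "ratios x", ncol(x$values),
      "samples\n")
  invisible(x)
}

#' Per-ratio fold change (median cases / median controls)
#'
#' @param rm a `ratio_matrix` (or plain matrix, features x samples).
#' @param labels case/control labels; defaults to those stored in `rm`.
#' @return named numeric vector of fold changes.
#' @export
fold_change <- function(rm, labels = NULL) {
  v <- if (inherits(rm, "ratio_matrix")) rm$values else as.matrix(rm)
  labels <- labels %||% rm$labels
  y <- label01(labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("fold change needs both cases and controls")
  med_case <- apply(v[, y == 1, drop = FALSE], 1, stats::median)
  med_ctrl <- apply(v[, y == 0, drop = FALSE], 1, stats::median)
  med_case / med_ctrl
}

#' Per-ratio coefficient of variation among controls
#'
#' Sample standard deviation over mean of the raw ratio values in
#' control samples; the stability gate of selection strategy 2.
#'
#' @inheritParams fold_change
#' @return named numeric vector of CVs (>= 0).
#' @export
control_cv <- function(rm, labels = NULL) {
  v <- if (inherits(rm, "ratio_matrix")) rm$values else as.matrix(rm)
  labels <- labels %||% rm$labels
  y <- label01(labels)
  if (sum(y == 0) < 2) stop("control CV needs >= 2 control samples")
  ctrl <- v[, y == 0, drop = FALSE]
  apply(ctrl, 1, stats::sd) / rowMeans(ctrl)
}
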