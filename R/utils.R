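# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# case/control labels -> 0/1 integer with "case" as the positive class
label01 <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lv <- c("control", "case")
  if (!all(labels %in% lv)) {
    stop("labels must be 'case' or 'control'; got: ",
         paste(setdiff(unique(labels), lv), collapse = ", "))
  }
  as.integer(labels == "case")
}

# locale-independent lexicographic sort (radix is byte-wise, deterministic)
lex_sort <- function(x) sort(x, method = "radix")

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds, separately within each
#' outcome class, so every fold keeps both cases and controls.
#'
#' @param y binary outcome (0/1 or case/control labels).
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the assignment.
#' @return integer vector of fold ids in 1..k, one per observation.
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  y <- label01(y)
  if (k < 2) stop("k must be >= 2")
  if (min(table(y)) < k) {
    stop("cannot stratify: a class has fewer observations (",
         min(table(y)), ") than folds (", k, ")")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# format a numeric for deterministic text output: 6 significant digits
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}
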