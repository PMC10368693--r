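#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] returning the U statistic
#' for `x` versus `y` and the two-sided p-value. The exact null
#' distribution is used when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. When every value in both groups is identical
#' the test is degenerate and p = 1 by convention.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `U`, `p` and `exact` (logical, which path was used).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n0 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = n1 * n0 / 2, p = 1, exact = FALSE))
  }
  use_exact <- (n1 + n0 <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = min(1, wt$p.value), exact = use_exact)
}

# Row-wise Mann-Whitney with the normal approximation (tie + continuity
# corrected), identical to wilcox.test's approximate path. Used for
# screening thousands of ratios at once; equality with wilcox.test is
# asserted in the test suite.
mw_rows_approx <- function(values, y) {
  y <- label01(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  N <- n1 + n0
  U <- numeric(nrow(values))
  p <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    r <- rank(values[i, ])
    u <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
    nt <- table(r)
    tie_term <- sum(nt^3 - nt)
    sigma2 <- (n1 * n0 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    z <- u - n1 * n0 / 2
    if (sigma2 <= 0) {
      U[i] <- u; p[i] <- 1
      next
    }
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    U[i] <- u
    p[i] <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction via [stats::p.adjust()],
#' with input validation.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-ratio differential statistics
#'
#' Mann-Whitney U and p for cases versus controls on every ratio
#' (normal approximation with tie and continuity correction — sample
#' sizes at screening scale are far beyond the exact regime),
#' Benjamini-Hochberg adjusted p, fold change (median cases / median
#' controls) and control coefficient of variation.
#'
#' @param rm a `ratio_matrix`.
#' @param labels optional labels overriding those stored in `rm`.
#' @return data.frame with columns `ratio_id`, `U`, `p`, `adj_p`, `fc`,
#'   `control_cv`, in the (deterministic) ratio order of `rm`.
#' @export
ratio_stats <- function(rm, labels = NULL) {
  labels <- labels %||% rm$labels
  y <- label01(labels)
  mw <- mw_rows_approx(rm$values, y)
  data.frame(
    ratio_id = rownames(rm$values),
    U = mw$U,
    p = mw$p,
    adj_p = bh_adjust(mw$p),
    fc = unname(fold_change(rm, labels)),
    control_cv = unname(control_cv(rm, labels)),
    stringsAsFactors = FALSE
  )
}

#' Selection strategy 1: significance plus fold-change gate
#'
#' Ratios with BH-adjusted p <= `alpha` and fold change > `fc_hi` or
#' < `fc_lo`.
#'
#' @param stats a `ratio_matrix` (statistics are computed) or the
#'   data.frame returned by [ratio_stats()].
#' @param labels labels, used only when `stats` is a `ratio_matrix`.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param fc_hi,fc_lo fold-change gates (defaults 2 and 0.5).
#' @return character vector of selected ratio ids.
#' @export
strategy1 <- function(stats, labels = NULL, alpha = 0.01, fc_hi = 2,
                      fc_lo = 0.5) {
  st <- if (inherits(stats, "ratio_matrix")) ratio_stats(stats, labels) else stats
  st$ratio_id[st$adj_p <= alpha & (st$fc > fc_hi | st$fc < fc_lo)]
}

#' Selection strategy 2: significance plus control-stability gate
#'
#' Ratios with BH-adjusted p <= `alpha` and coefficient of variation
#' among controls < `cv_max`; no fold-change criterion.
#'
#' @inheritParams strategy1
#' @param cv_max control-CV gate (default 0.5).
#' @return character vector of selected ratio ids.
#' @export
strategy2 <- function(stats, labels = NULL, alpha = 0.01, cv_max = 0.5) {
  st <- if (inherits(stats, "ratio_matrix")) ratio_stats(stats, labels) else stats
  st$ratio_id[st$adj_p <= alpha & st$control_cv < cv_max]
}

#' Configuration for the penalised logistic signature fit
#'
#' @param lambda `"auto"` (cross-validated search) or a fixed
#'   non-negative penalty.
#' @param nfolds folds for the lambda search (>= 2).
#' @param seed seed controlling fold assignment.
#' @param standardize standardize features to zero mean / unit variance
#'   before fitting (coefficients are returned on the unstandardized
#'   scale).
#' @param log2 log2-transform features before fitting (use for raw-scale
#'   ratios; delta-Ct features are already on a log2 scale).
#' @param rule `"min"` (lambda minimising mean CV binomial deviance) or
#'   `"1se"` (largest lambda within one standard error of the minimum).
#' @return list of class `lasso_config`.
#' @export
lasso_config <- function(lambda = "auto", nfolds = 5, seed = 1,
                         standardize = TRUE, log2 = FALSE,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (!identical(lambda, "auto") && (!is.numeric(lambda) || lambda < 0))
    stop("lambda must be \"auto\" or a non-negative number")
  if (nfolds < 2) stop("nfolds must be >= 2")
  structure(list(lambda = lambda, nfolds = nfolds, seed = seed,
                 standardize = standardize, log2 = log2, rule = rule),
            class = "lasso_config")
}

prepare_design <- function(X, cfg) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (cfg$log2) {
    if (any(X <= 0)) stop("log2 transform requires strictly positive features")
    X <- log2(X)
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mu <- colMeans(X)
  if (cfg$standardize) {
    Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
    scl <- sds
  } else {
    Xs <- X
    mu <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    names(mu) <- names(scl) <- colnames(X)
  }
  list(Xs = Xs, mu = mu, scl = scl, dropped = dropped)
}

# glmnet needs >= 2 columns; pad with an all-zero dummy when p == 1
with_glmnet_pad <- function(Xs) {
  if (ncol(Xs) >= 2) return(list(X = Xs, padded = FALSE))
  list(X = cbind(Xs, `.pad` = 0), padded = TRUE)
}

#' Select the L1 penalty by cross-validated binomial deviance
#'
#' Stratified fold assignment under the configured seed, then
#' [glmnet::cv.glmnet()] over its logarithmic lambda grid; the grid and
#' per-lambda mean deviances are returned for audit.
#'
#' @param X feature matrix (transformed per `cfg` before the search).
#' @param y binary outcome (0/1 or case/control).
#' @param cfg a [lasso_config()].
#' @return list with `lambda` (chosen), `lambda_min`, `lambda_1se`,
#'   `grid`, `cvm` (mean CV deviance per grid point).
#' @export
select_lambda <- function(X, y, cfg = lasso_config()) {
  y <- label01(y)
  prep <- prepare_design(X, cfg)
  pad <- with_glmnet_pad(prep$Xs)
  foldid <- stratified_folds(y, cfg$nfolds, cfg$seed)
  cvfit <- glmnet::cv.glmnet(pad$X, y, family = "binomial", foldid = foldid,
                             standardize = FALSE, type.measure = "deviance")
  lam <- if (cfg$rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  list(lambda = lam, lambda_min = cvfit$lambda.min,
       lambda_1se = cvfit$lambda.1se, grid = cvfit$lambda, cvm = cvfit$cvm)
}

#' Fit the L1-penalised logistic signature model
#'
#' Features are (optionally) log2-transformed and standardized, the
#' penalised binomial likelihood is maximised with an unpenalised
#' intercept, and coefficients are mapped back to the unstandardized
#' feature scale. Features with a zero coefficient are reported as
#' unselected.
#'
#' @param X feature matrix (samples x features).
#' @param y binary outcome (0/1 or case/control labels).
#' @param cfg a [lasso_config()].
#' @return object of class `signature_model`: `feature_names`,
#'   `coefficients` (unstandardized scale, zeros retained), `intercept`,
#'   `selected` (names of non-zero features), `lambda`, `means`,
#'   `scales`, `std_coefficients` (standardized scale, for optimality
#'   diagnostics), `log2`, `lambda_search` (audit trail when lambda was
#'   selected automatically).
#' @export
fit_lasso_logistic <- function(X, y, cfg = lasso_config()) {
  y <- label01(y)
  prep <- prepare_design(X, cfg)
  Xs <- prep$Xs
  search <- NULL
  lambda <- cfg$lambda
  if (identical(lambda, "auto")) {
    search <- select_lambda(X, y, cfg)
    lambda <- search$lambda
  }
  pad <- with_glmnet_pad(Xs)
  n <- nrow(Xs)
  lam_max <- max(abs(crossprod(pad$X, y - mean(y))) / n, lambda, 1e-4)
  grid <- exp(seq(log(lam_max * 1.05), log(max(lam_max * 1e-4, 1e-8)),
                  length.out = 80))
  grid <- sort(unique(c(grid, lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(pad$X, y, family = "binomial", lambda = grid,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda))
  a <- cf[1]
  b_std <- cf[-1]
  if (pad$padded) b_std <- b_std[-length(b_std)]
  names(b_std) <- colnames(Xs)
  b <- b_std / prep$scl
  intercept <- a - sum(b_std * prep$mu / prep$scl)
  structure(
    list(feature_names = colnames(Xs),
         coefficients = b,
         intercept = intercept,
         selected = names(b)[b_std != 0],
         lambda = lambda,
         means = prep$mu,
         scales = prep$scl,
         std_coefficients = b_std,
         std_intercept = a,
         dropped = prep$dropped,
         log2 = cfg$log2,
         lambda_search = search),
    class = "signature_model"
  )
}

#' Predicted case probabilities from a signature model
#'
#' @param object a `signature_model`.
#' @param newdata feature matrix on the raw input scale (the model's
#'   log2 transform, if any, is applied internally); columns must cover
#'   the model's feature names.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.signature_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X)) && ncol(X) == length(object$feature_names))
    colnames(X) <- object$feature_names
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss) > 0)
    stop("newdata lacks model features: ", paste(miss, collapse = ", "))
  X <- X[, object$feature_names, drop = FALSE]
  if (object$log2) X <- log2(X)
  eta <- object$intercept + drop(X %*% object$coefficients)
  stats::plogis(eta)
}

#' @exportS3Method base::print
print.signature_model <- function(x, ...) {
  cat("signature_model: lambda =", signif(x$lambda, 4), "|",
      length(x$selected), "of", length(x$feature_names),
      "features selected\n")
  if (length(x$selected) > 0) {
    print(round(x$coefficients[x$selected], 4))
  }
  invisible(x)
}
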