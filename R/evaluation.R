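clamp_prob <- function(p, eps = 1e-12) pmin(1 - eps, pmax(eps, p))

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half, for "case"
#' (y = 1) as the positive class. Constant predictions give 0.5.
#'
#' @param p_hat numeric scores or probabilities.
#' @param y binary outcome (0/1 or case/control labels).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(p_hat, y) {
  y <- label01(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(p_hat)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_obj <- function(p_hat, y) {
  pROC::roc(response = label01(y), predictor = as.numeric(p_hat),
            levels = c(0, 1), direction = "<", quiet = TRUE)
}

#' AUC with DeLong 95\% confidence interval
#'
#' @inheritParams auc
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`.
#' @export
auc_ci <- function(p_hat, y, conf = 0.95) {
  ci <- as.numeric(pROC::ci.auc(roc_obj(p_hat, y), conf.level = conf,
                                method = "delong"))
  list(auc = auc(p_hat, y), ci_low = ci[1], ci_high = ci[3])
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score vectors must be computed on the same samples; the Z
#' statistic uses the DeLong structural-component covariance. Identical
#' score vectors give Z = 0, p = 1.
#'
#' @param p1,p2 score vectors on the same samples.
#' @param y binary outcome.
#' @return list with `auc1`, `auc2`, `Z`, `p`.
#' @export
delong_paired_test <- function(p1, p2, y) {
  a1 <- auc(p1, y); a2 <- auc(p2, y)
  if (isTRUE(all.equal(as.numeric(p1), as.numeric(p2)))) {
    return(list(auc1 = a1, auc2 = a2, Z = 0, p = 1))
  }
  rt <- pROC::roc.test(roc_obj(p1, y), roc_obj(p2, y), method = "delong",
                       paired = TRUE)
  list(auc1 = a1, auc2 = a2, Z = unname(rt$statistic), p = rt$p.value)
}

#' Calibration intercept (calibration-in-the-large)
#'
#' Intercept of the logistic recalibration model
#' `logit P(y = 1) = a + logit(p_hat)` with the slope fixed at 1
#' (the prediction enters as an offset). Ideal value 0.
#'
#' @param p_hat predicted probabilities in (0, 1).
#' @param y binary outcome.
#' @return the intercept `a`.
#' @export
calibration_intercept <- function(p_hat, y) {
  y <- label01(y)
  lp <- stats::qlogis(clamp_prob(p_hat))
  fit <- stats::glm(y ~ 1, family = stats::binomial(), offset = lp)
  unname(stats::coef(fit)[1])
}

#' Calibration slope (Cox's measure of spread)
#'
#' Slope `b` of `logit P(y = 1) = a + b * logit(p_hat)`, both free.
#' Ideal value 1; b < 1 means predictions are too extreme (too high for
#' high-risk, too low for low-risk subjects), b > 1 too moderate.
#'
#' @inheritParams calibration_intercept
#' @return the slope `b`.
#' @export
calibration_slope <- function(p_hat, y) {
  y <- label01(y)
  lp <- stats::qlogis(clamp_prob(p_hat))
  if (stats::sd(lp) == 0)
    stop("calibration slope undefined for constant predictions")
  fit <- stats::glm(y ~ lp, family = stats::binomial())
  unname(stats::coef(fit)[2])
}

#' Scaled Brier score
#'
#' Mean squared prediction error divided by the Brier score of the
#' uninformative constant predictor (the outcome prevalence), so 0 is
#' perfect and 1 matches the null model. `type = "ipa"` gives the
#' complementary index of prediction accuracy, 1 - scaled.
#'
#' @inheritParams calibration_intercept
#' @param type `"scaled"` (default) or `"ipa"`.
#' @return a single number.
#' @export
scaled_brier <- function(p_hat, y, type = c("scaled", "ipa")) {
  type <- match.arg(type)
  y <- label01(y)
  if (length(unique(y)) < 2) stop("scaled Brier needs both classes present")
  brier <- mean((p_hat - y)^2)
  prev <- mean(y)
  brier_null <- mean((prev - y)^2)
  s <- brier / brier_null
  if (type == "scaled") s else 1 - s
}

#' Youden-index cut-off on predicted probabilities
#'
#' Candidate cut-offs are midpoints between adjacent sorted unique
#' predictions (plus below-minimum and above-maximum sentinels); a
#' sample is classified positive when its prediction is >= the cut-off.
#' The cut-off maximising J = sensitivity + specificity - 1 is
#' returned, ties broken toward the larger cut-off (higher
#' specificity).
#'
#' @inheritParams auc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(p_hat, y) {
  y <- label01(y)
  if (sum(y) == 0 || sum(y) == length(y)) stop("both classes required")
  u <- sort(unique(p_hat))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  best <- NULL
  for (ct in cand) {
    pos <- p_hat >= ct
    sens <- sum(pos & y == 1) / n1
    spec <- sum(!pos & y == 0) / n0
    j <- sens + spec - 1
    # candidates are increasing, so ">= (within fp tolerance)" breaks
    # ties toward the larger cut-off
    if (is.null(best) || j >= best$youden - 1e-12) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   youden = j)
    }
  }
  best
}

#' Univariate odds ratios by standard logistic regression
#'
#' For a categorical exposure: one OR per non-reference level versus the
#' reference, with Wald 95\% CI and p. For a 2x2 layout this maximum-
#' likelihood OR equals the cross-product ratio. For a continuous
#' exposure: OR per unit. Zero cells are reported with a note rather
#' than silently corrected.
#'
#' @param exposure factor/character/numeric exposure.
#' @param y binary outcome (0/1 or case/control labels).
#' @param reference reference level for categorical exposures (default:
#'   first sorted level).
#' @param continuous treat the exposure as continuous.
#' @param conf confidence level for the Wald CI (default 0.95).
#' @return data.frame with `level`, `or`, `ci_low`, `ci_high`, `p`,
#'   `note`.
#' @export
univariate_or <- function(exposure, y, reference = NULL, continuous = FALSE,
                          conf = 0.95) {
  y <- label01(y)
  keep <- !is.na(exposure) & !is.na(y)
  exposure <- exposure[keep]; y <- y[keep]
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  # capture separation / non-convergence as a structured note rather
  # than raw glm warnings
  glm_note <- ""
  quiet_glm <- function(...) {
    withCallingHandlers(
      stats::glm(...),
      warning = function(w) {
        glm_note <<- "separation or non-convergence: estimate unstable"
        invokeRestart("muffleWarning")
      })
  }
  if (continuous) {
    fit <- quiet_glm(y ~ exposure, family = stats::binomial())
    est <- stats::coef(summary(fit))["exposure", ]
    return(data.frame(level = "per unit", or = exp(est["Estimate"]),
                      ci_low = exp(est["Estimate"] - zcrit * est["Std. Error"]),
                      ci_high = exp(est["Estimate"] + zcrit * est["Std. Error"]),
                      p = est["Pr(>|z|)"], note = glm_note, row.names = NULL))
  }
  f <- factor(exposure)
  if (!is.null(reference)) f <- stats::relevel(f, ref = as.character(reference))
  if (nlevels(f) < 2) stop("categorical exposure needs >= 2 levels")
  zero_cells <- any(table(f, y) == 0)
  fit <- quiet_glm(y ~ f, family = stats::binomial())
  sm <- stats::coef(summary(fit))
  rows <- grep("^f", rownames(sm))
  data.frame(
    level = sub("^f", "", rownames(sm)[rows]),
    or = exp(sm[rows, "Estimate"]),
    ci_low = exp(sm[rows, "Estimate"] - zcrit * sm[rows, "Std. Error"]),
    ci_high = exp(sm[rows, "Estimate"] + zcrit * sm[rows, "Std. Error"]),
    p = sm[rows, "Pr(>|z|)"],
    note = if (zero_cells) "zero cell: estimate unstable" else glm_note,
    row.names = NULL
  )
}

#' Odds ratio from a 2x2 table of counts
#'
#' Cross-product ratio with the classical Wald CI
#' (`exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`). Convenience for
#' worked examples quoted from published count tables.
#'
#' @param case_exposed,case_ref,control_exposed,control_ref cell counts.
#' @param conf confidence level.
#' @return data.frame with `or`, `ci_low`, `ci_high`.
#' @export
or_from_counts <- function(case_exposed, case_ref, control_exposed,
                           control_ref, conf = 0.95) {
  or <- (case_exposed * control_ref) / (control_exposed * case_ref)
  se <- sqrt(1 / case_exposed + 1 / case_ref + 1 / control_exposed +
               1 / control_ref)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(or = or, ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se))
}

#' Cochran-Armitage trend test for an ordinal exposure
#'
#' Two-sided chi-square (1 df) test for a linear trend in the case
#' proportion over the ordered exposure levels, with equally spaced
#' scores, via [stats::prop.trend.test()].
#'
#' @param exposure ordinal exposure (integer-scored levels).
#' @param y binary outcome.
#' @return two-sided p-value.
#' @export
cochran_armitage <- function(exposure, y) {
  y <- label01(y)
  keep <- !is.na(exposure)
  exposure <- exposure[keep]; y <- y[keep]
  lv <- sort(unique(exposure))
  if (length(lv) < 2) stop("trend test needs >= 2 exposure levels")
  events <- vapply(lv, function(l) sum(y[exposure == l]), numeric(1))
  totals <- vapply(lv, function(l) sum(exposure == l), numeric(1))
  stats::prop.trend.test(events, totals, score = lv)$p.value
}

#' Stratified k-fold cross-validated performance
#'
#' For each fold the model is fitted on the remaining folds and held-out
#' probabilities are scored with the four performance measures:
#' calibration intercept, calibration slope, scaled Brier and AUC.
#' When a `selector` is supplied, feature selection is re-run inside
#' every training fold (the defensible default for a selection-plus-
#' model pipeline) and the model sees only the selected columns; a fold
#' whose selector returns nothing falls back to the training prevalence
#' (its AUC is 0.5 and its calibration slope is undefined, reported NA).
#'
#' @param X feature matrix (samples x features) on the raw input scale.
#' @param y binary outcome.
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @param cfg [lasso_config()] for the per-fold fits.
#' @param selector optional `function(X_train, y_train) -> column names`
#'   run inside each training fold.
#' @return list of class `cv_performance`: `folds` (per-fold
#'   data.frame) and `mean` (named vector of fold averages, NA-robust).
#' @export
kfold_cv <- function(X, y, k = 5, seed = 1, cfg = lasso_config(),
                     selector = NULL) {
  X <- as.matrix(X)
  y <- label01(y)
  foldid <- stratified_folds(y, k, seed)
  rows <- lapply(seq_len(k), function(fold) {
    tr <- foldid != fold
    te <- !tr
    feats <- if (is.null(selector)) colnames(X) else selector(X[tr, , drop = FALSE], y[tr])
    if (length(feats) == 0) {
      p <- rep(mean(y[tr]), sum(te))
    } else {
      m <- fit_lasso_logistic(X[tr, feats, drop = FALSE], y[tr], cfg)
      p <- predict(m, X[te, feats, drop = FALSE])
    }
    yt <- y[te]
    slope <- if (stats::sd(stats::qlogis(clamp_prob(p))) == 0) NA_real_ else
      calibration_slope(p, yt)
    data.frame(fold = fold,
               n_features = length(feats),
               calibration_intercept = calibration_intercept(p, yt),
               calibration_slope = slope,
               scaled_brier = scaled_brier(p, yt),
               auc = auc(p, yt))
  })
  folds <- do.call(rbind, rows)
  means <- colMeans(folds[, c("calibration_intercept", "calibration_slope",
                              "scaled_brier", "auc")], na.rm = TRUE)
  structure(list(folds = folds, mean = means), class = "cv_performance")
}

#' @exportS3Method base::print
print.cv_performance <- function(x, ...) {
  cat("cross-validated performance (mean over", nrow(x$folds), "folds):\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Fit the combined ratio + risk-factor model
#'
#' Design matrix: the candidate ratio features plus breast-density class
#' (continuous ordinal score), lifestyle score (continuous), an
#' indicator of BMI >= 30, a menopause indicator, and the
#' BMI-class-by-menopause product term. Complete cases only; the number
#' of dropped rows is reported via a message.
#'
#' @param ratios matrix of ratio features (samples x ratios), already on
#'   their analysis scale (e.g. delta-Ct).
#' @param covariates data.frame with columns `tabar`, `wcrf`, `bmi` (or
#'   a precomputed `bmi30`), `menopause`.
#' @param y binary outcome.
#' @param cfg [lasso_config()] (log2 should be FALSE for delta-Ct
#'   features).
#' @return a `signature_model` fitted on the combined design.
#' @export
fit_combined_model <- function(ratios, covariates, y, cfg = lasso_config()) {
  ratios <- as.matrix(ratios)
  y <- label01(y)
  bmi30 <- if ("bmi30" %in% names(covariates)) as.numeric(covariates$bmi30)
  else as.numeric(covariates$bmi >= 30)
  men <- as.numeric(covariates$menopause)
  design <- cbind(ratios,
                  tabar = as.numeric(covariates$tabar),
                  wcrf = as.numeric(covariates$wcrf),
                  bmi30 = bmi30,
                  menopause = men,
                  bmi30_x_menopause = bmi30 * men)
  cc <- stats::complete.cases(design)
  if (!all(cc)) message("dropping ", sum(!cc), " incomplete case(s)")
  if (!any(cc)) stop("no complete cases in combined design")
  fit_lasso_logistic(design[cc, , drop = FALSE], y[cc], cfg)
}
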