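#' Discovery-stage configuration
#'
#' Defaults are the study's stated analysis parameters: mean-count
#' filter 20, adjusted-p threshold 0.01, fold-change gates 2 / 0.5,
#' control-CV gate 0.5, five CV folds.
#'
#' @param min_mean mean-count retention threshold (strict `>`).
#' @param pseudocount pseudocount for ratio construction.
#' @param dedup_tolerance profile-identity tolerance (0 = exact).
#' @param alpha adjusted-p threshold for both strategies.
#' @param fc_hi,fc_lo strategy-1 fold-change gates.
#' @param cv_max strategy-2 control-CV gate.
#' @param folds cross-validation folds.
#' @param seed seed for fold assignment and the lambda search.
#' @param lasso a [lasso_config()]; defaults to log2-transformed,
#'   standardized features with the cross-validated lambda.
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(min_mean = 20, pseudocount = 1,
                             dedup_tolerance = 0, alpha = 0.01, fc_hi = 2,
                             fc_lo = 0.5, cv_max = 0.5, folds = 5, seed = 1,
                             lasso = NULL) {
  lasso <- lasso %||% lasso_config(log2 = TRUE, seed = seed, nfolds = folds)
  structure(list(min_mean = min_mean, pseudocount = pseudocount,
                 dedup_tolerance = dedup_tolerance, alpha = alpha,
                 fc_hi = fc_hi, fc_lo = fc_lo, cv_max = cv_max,
                 folds = folds, seed = seed, lasso = lasso),
            class = "discovery_config")
}

# selector factory: re-runs the screening strategies on a training
# subset (features are raw-scale ratio values, samples x ratios)
make_strategy_selector <- function(strategy = c("strategy1", "strategy2",
                                                "union"),
                                   alpha = 0.01, fc_hi = 2, fc_lo = 0.5,
                                   cv_max = 0.5) {
  strategy <- match.arg(strategy)
  function(X_train, y_train) {
    rm <- structure(list(values = t(X_train),
                         sample_ids = rownames(X_train),
                         labels = y_train),
                    class = "ratio_matrix")
    st <- ratio_stats(rm, y_train)
    s1 <- strategy1(st, alpha = alpha, fc_hi = fc_hi, fc_lo = fc_lo)
    s2 <- strategy2(st, alpha = alpha, cv_max = cv_max)
    switch(strategy, strategy1 = s1, strategy2 = s2,
           union = union(s1, s2))
  }
}

#' Run the discovery stage
#'
#' filter by mean count, collapse identical profiles, build all-pairs
#' ratios, screen with both strategies, fit a penalised logistic
#' signature per strategy, and assess each by stratified k-fold
#' cross-validation with the screening re-run inside every training
#' fold (so CV estimates carry no selection optimism).
#'
#' @param cm a [count_matrix()].
#' @param cfg a [discovery_config()].
#' @param run_cv set FALSE to skip the cross-validation stage.
#' @param cv_strategies which strategies to cross-validate (default
#'   both).
#' @return list with `dims` (stage-by-stage dimensions), `filtered`,
#'   `dedup_map`, `ratios` (the `ratio_matrix`), `stats`, `strategy1`,
#'   `strategy2`, `union` (screened ratio ids), `models` and
#'   `lasso_selected` (per strategy), `cv` (per-strategy
#'   `cv_performance`).
#' @export
run_discovery <- function(cm, cfg = discovery_config(), run_cv = TRUE,
                          cv_strategies = c("strategy1", "strategy2")) {
  filtered <- filter_mirs(cm, cfg$min_mean)
  dd <- deduplicate_profiles(filtered, cfg$dedup_tolerance)
  rm <- build_ratio_matrix(dd$cm, cfg$pseudocount)
  st <- ratio_stats(rm)
  s1 <- strategy1(st, alpha = cfg$alpha, fc_hi = cfg$fc_hi, fc_lo = cfg$fc_lo)
  s2 <- strategy2(st, alpha = cfg$alpha, cv_max = cfg$cv_max)
  st$strategy1 <- st$ratio_id %in% s1
  st$strategy2 <- st$ratio_id %in% s2

  y <- label01(rm$labels)
  X <- t(rm$values)
  fit_one <- function(ids) {
    if (length(ids) == 0) return(NULL)
    fit_lasso_logistic(X[, ids, drop = FALSE], y, cfg$lasso)
  }
  models <- list(strategy1 = fit_one(s1), strategy2 = fit_one(s2))
  lasso_selected <- lapply(models, function(m) if (is.null(m)) character(0)
                           else m$selected)
  cv <- NULL
  if (run_cv) {
    cv_strategies <- match.arg(cv_strategies, several.ok = TRUE)
    cv <- lapply(stats::setNames(cv_strategies, cv_strategies),
                 function(s) {
                   sel <- make_strategy_selector(s, cfg$alpha, cfg$fc_hi,
                                                 cfg$fc_lo, cfg$cv_max)
                   kfold_cv(X, y, k = cfg$folds, seed = cfg$seed,
                            cfg = cfg$lasso, selector = sel)
                 })
  }
  list(dims = list(input_mirs = length(cm$mir_ids),
                   samples = length(cm$sample_ids),
                   filtered_mirs = length(filtered$mir_ids),
                   unique_mirs = length(dd$cm$mir_ids),
                   n_ratios = nrow(rm$values),
                   n_strategy1 = length(s1), n_strategy2 = length(s2),
                   n_union = length(union(s1, s2))),
       filtered = filtered, dedup_map = dd$map, ratios = rm, stats = st,
       strategy1 = s1, strategy2 = s2, union = union(s1, s2),
       models = models, lasso_selected = lasso_selected, cv = cv)
}

#' Run the cross-platform validation stage
#'
#' Triplicate QC on the Ct plates, mapping of the sequencing-selected
#' ratios to mature-miR assays, per-sample delta-Ct ratios, a
#' per-ratio univariate table (OR per delta-Ct unit with Wald CI, and
#' AUC), and Spearman concordance against the sequencing log2 ratios.
#'
#' @param plates long-format Ct data.frame ([read_ct_plates()]).
#' @param selected_ratio_ids sequencing-stage ratio ids to validate.
#' @param seq_rm the sequencing `ratio_matrix` (for concordance).
#' @param labels named case/control labels covering the qPCR samples.
#' @param exclusions assay-level manual exclusion list.
#' @param concordance_alpha significance gate for the concordant flag.
#' @param nondetect_ct imputed Ct for non-detects.
#' @return list with `ct_means`, `map`, `dct` (delta-Ct matrix),
#'   `table` (per-ratio OR / AUC data.frame), `concordance`.
#' @export
run_validation <- function(plates, selected_ratio_ids, seq_rm, labels,
                           exclusions = character(0),
                           concordance_alpha = 0.01, nondetect_ct = 40) {
  ctm <- qc_ct_plates(plates, nondetect_ct)
  map <- map_sequencing_ratios_to_assays(selected_ratio_ids, exclusions)
  dct <- delta_ct_matrix(ctm, map$ratios)
  y <- label01(labels[colnames(dct)])

  tab <- do.call(rbind, lapply(seq_len(nrow(dct)), function(i) {
    v <- dct[i, ]
    or <- univariate_or(v, y, continuous = TRUE)
    data.frame(ratio_id = rownames(dct)[i], or = or$or, ci_low = or$ci_low,
               ci_high = or$ci_high, p = or$p, auc = auc(v, y),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  # sequencing values for the mapped ratios, on the log2 scale,
  # keyed by assay-level ratio id (first source ratio per assay)
  src <- vapply(strsplit(map$ratios$source_ids, ";", fixed = TRUE),
                `[`, character(1), 1)
  seq_log <- log2(seq_rm$values[src, , drop = FALSE])
  rownames(seq_log) <- map$ratios$ratio_id
  conc <- cross_platform_concordance(seq_log, dct, concordance_alpha)

  list(ct_means = ctm, map = map, dct = dct, table = tab,
       concordance = conc)
}

#' Run the combined-modelling stage
#'
#' Fits the three penalised logistic models — ratios only, ratios plus
#' risk factors (density class, lifestyle score, BMI>=30, menopause and
#' their product), and risk factors only — on the complete-case
#' samples, and reports AUC with DeLong CI, the Youden cut-off with its
#' sensitivity and specificity, and all pairwise paired DeLong
#' comparisons.
#'
#' @param dct delta-Ct ratio matrix (ratios x samples).
#' @param covariates data.frame with `sample_id`, `tabar`, `wcrf`,
#'   `bmi` (or `bmi30`), `menopause`.
#' @param labels named case/control labels.
#' @param cfg a [lasso_config()] (delta-Ct features are already
#'   log2-scale, so `log2 = FALSE`).
#' @return list with `models`, `metrics` (per-model list: auc, ci,
#'   cutoff, sensitivity, specificity), `delong` (pairwise data.frame),
#'   `n_used`, `n_dropped`.
#' @export
run_combined <- function(dct, covariates, labels, cfg = lasso_config()) {
  samples <- intersect(colnames(dct), covariates$sample_id)
  cov <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  Xr <- t(dct[, samples, drop = FALSE])
  y <- label01(labels[samples])
  bmi30 <- if ("bmi30" %in% names(cov)) as.numeric(cov$bmi30)
  else as.numeric(cov$bmi >= 30)
  nonmol <- cbind(tabar = as.numeric(cov$tabar),
                  wcrf = as.numeric(cov$wcrf),
                  bmi30 = bmi30,
                  menopause = as.numeric(cov$menopause),
                  bmi30_x_menopause = bmi30 * as.numeric(cov$menopause))
  cc <- stats::complete.cases(cbind(Xr, nonmol))
  n_dropped <- sum(!cc)
  if (n_dropped > 0) message("dropping ", n_dropped, " incomplete case(s)")
  Xr <- Xr[cc, , drop = FALSE]; nonmol <- nonmol[cc, , drop = FALSE]
  y <- y[cc]; cov <- cov[cc, , drop = FALSE]

  models <- list(
    ratios = fit_lasso_logistic(Xr, y, cfg),
    combined = fit_combined_model(Xr, cov, y, cfg),
    nonmolecular = fit_lasso_logistic(nonmol, y, cfg)
  )
  designs <- list(ratios = Xr, combined = cbind(Xr, nonmol),
                  nonmolecular = nonmol)
  preds <- lapply(names(models), function(nm)
    predict(models[[nm]], designs[[nm]]))
  names(preds) <- names(models)
  metrics <- lapply(names(models), function(nm) {
    p <- preds[[nm]]
    ci <- auc_ci(p, y)
    yc <- youden_cutoff(p, y)
    list(model = nm, auc = ci$auc, auc_ci = c(ci$ci_low, ci$ci_high),
         cutoff = yc$cutoff, sensitivity = yc$sensitivity,
         specificity = yc$specificity, youden = yc$youden)
  })
  names(metrics) <- names(models)
  pairs <- utils::combn(names(models), 2)
  delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dt <- delong_paired_test(preds[[a]], preds[[b]], y)
    data.frame(model1 = a, model2 = b, auc1 = dt$auc1, auc2 = dt$auc2,
               Z = dt$Z, p = dt$p, stringsAsFactors = FALSE)
  }))
  list(models = models, predictions = preds, metrics = metrics,
       delong = delong, n_used = sum(cc), n_dropped = n_dropped)
}
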