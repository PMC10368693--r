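#!/usr/bin/env Rscript
# Stage 4 — combined modelling and model comparison.
#
# Fits the three penalised logistic models on the qPCR delta-Ct ratios
# and the covariates (density class, lifestyle score, BMI >= 30,
# menopause and their interaction): ratios only, combined, and
# risk factors only. Reports AUC with DeLong CI, the Youden cut-off
# with sensitivity/specificity, and the pairwise paired DeLong
# comparisons. Also computes the per-sample PRS and its univariate
# association. Writes metrics under results/combined/.

suppressPackageStartupMessages(library(miRatio))

cov <- utils::read.delim("results/synthetic/covariates.tsv")
geno <- utils::read.delim("results/synthetic/genotypes.tsv",
                          check.names = FALSE)
weights <- read_panel_weights("results/synthetic/snp_weights.tsv")
labels <- with(cov, stats::setNames(label, sample_id))

gm <- as.matrix(geno[, -1]); rownames(gm) <- geno$sample_id
prs <- compute_prs(gm, weights)
cat("PRS computed for", nrow(prs), "samples;",
    sum(prs$n_missing > 0), "samples have missing genotypes\n")
y <- as.integer(labels[prs$sample_id] == "case")
or_prs <- univariate_or(prs$prs, y, continuous = TRUE)
cat("PRS univariate OR per unit:", round(or_prs$or, 2), " (95% CI",
    round(or_prs$ci_low, 2), "-", round(or_prs$ci_high, 2), ")\n")

dct_df <- utils::read.delim("results/validation/delta_ct_ratios.tsv",
                            check.names = FALSE)
dct <- as.matrix(dct_df[, -1]); rownames(dct) <- dct_df$ratio_id

res <- run_combined(dct, cov, labels, lasso_config(seed = 20260921))
for (nm in names(res$metrics)) {
  m <- res$metrics[[nm]]
  cat(sprintf("%-13s AUC %.3f (%.3f-%.3f) | cutoff %.3f sens %.1f%% spec %.1f%%\n",
              nm, m$auc, m$auc_ci[1], m$auc_ci[2], m$cutoff,
              100 * m$sensitivity, 100 * m$specificity))
}
cat("pairwise DeLong comparisons:\n")
print(res$delong, row.names = FALSE, digits = 3)

dir.create("results/combined", recursive = TRUE, showWarnings = FALSE)
write_metrics_json(list(metrics = res$metrics,
                        delong = res$delong,
                        prs_or = as.list(or_prs[c("or", "ci_low", "ci_high",
                                                  "p")]),
                        n_used = res$n_used, n_dropped = res$n_dropped),
                   "results/combined/model_metrics.json")
write_stats_tsv(prs, "results/combined/prs.tsv")
cat("wrote results/combined/\n")
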