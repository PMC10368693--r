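#!/usr/bin/env Rscript
# Stage 3 — cross-platform validation on the qPCR arm.
#
# Applies triplicate QC (non-detects to Ct 40, one-sd trimming) to the
# simulated plates, maps the sequencing-selected ratios to mature-miR
# assays (collapsing duplicate loci), computes per-sample delta-Ct
# ratios, and reports the per-ratio univariable OR/AUC table plus
# Spearman concordance between the two platforms. Writes tables under
# results/validation/.

suppressPackageStartupMessages(library(miRatio))

cm <- read_count_matrix("results/synthetic/counts.tsv",
                        "results/synthetic/labels.tsv")
plates <- read_ct_plates("results/synthetic/ct_plates.tsv")
selected <- readLines("results/discovery/selected_ratios.txt")

# rebuild the sequencing ratio matrix for the concordance comparison
d <- run_discovery(cm, discovery_config(seed = 20260921), run_cv = FALSE)
v <- run_validation(plates, selected, d$ratios, cm$labels)

cat("QC:", nrow(v$ct_means), "(sample, assay) means;",
    sum(v$ct_means$n_excluded), "replicates trimmed;",
    sum(v$ct_means$all_nondetect), "all-non-detect wells\n")
cat("mapped", length(selected), "sequencing ratios to",
    nrow(v$map$ratios), "assay ratios over", length(v$map$mirs),
    "mature miRs\n")
cat("concordant ratios (Spearman p < 0.01, rho > 0):",
    sum(v$concordance$concordant), "of", nrow(v$concordance),
    "; rho range", paste(round(range(v$concordance$rho), 2),
                         collapse = " to "), "\n")
top <- v$table[order(v$table$p), ][1:5, c("ratio_id", "or", "p", "auc")]
cat("strongest univariable ratios on the qPCR scale:\n")
print(top, row.names = FALSE, digits = 3)

dir.create("results/validation", recursive = TRUE, showWarnings = FALSE)
write_stats_tsv(v$table, "results/validation/univariable_ratios.tsv")
write_stats_tsv(v$concordance, "results/validation/concordance.tsv")
dct_df <- data.frame(ratio_id = rownames(v$dct), v$dct, check.names = FALSE)
write_stats_tsv(dct_df, "results/validation/delta_ct_ratios.tsv")
cat("wrote results/validation/\n")
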