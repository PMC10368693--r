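# miRatio

Normalization-free circulating miRNA **ratio** biomarker discovery and
cross-platform validation for nested case–control screening studies, with a
synthetic cohort generator so the entire pipeline runs and is verifiable
without any external data.

## The problem and the method

Absolute circulating miRNA abundances from plasma small-RNA sequencing are
confounded by library size, input volume and extraction efficiency, and
RT-qPCR validation normally requires a normalizer gene that may itself vary.
This package instead uses **within-sample ratios**: for raw counts
`c_i`, `c_j` of two miRs in the same sample, the feature is

    r_ij = (c_i + 1) / (c_j + 1)

(pseudocount 1; the numerator is the lexicographically smaller miR id).
Any per-sample scaling factor cancels exactly, so no normalization is needed
on either platform. The pipeline:

1. **Filter / deduplicate** — keep miRs with across-sample mean raw count
   strictly greater than 20; collapse miRs with identical count profiles
   under a merged identifier; build all `n(n-1)/2` pairwise ratios.
2. **Screen** — per-ratio Mann–Whitney test (cases vs controls) with
   Benjamini–Hochberg correction; *strategy 1* keeps ratios with adjusted
   p ≤ 0.01 and fold change (median cases / median controls) > 2 or < 0.5;
   *strategy 2* keeps ratios with adjusted p ≤ 0.01 and coefficient of
   variation < 0.5 among controls.
3. **Select** — L1-penalised (LASSO) logistic regression on log2 ratios,
   penalty chosen by cross-validated binomial deviance; performance assessed
   by stratified 5-fold CV reporting calibration intercept, calibration
   (Cox) slope, scaled Brier score and AUC, with the screening re-run
   inside every training fold.
4. **Validate by RT-qPCR** — triplicate Ct QC (non-detects → Ct 40; any
   replicate more than one sd from the triplicate mean is trimmed, single
   pass), then the ratio of miR X over miR Y is measured as
   `ΔCt = Ct_mean(Y) − Ct_mean(X)` ≈ log2 abundance ratio; concordance
   between platforms is the per-ratio Spearman correlation.
5. **Combine** — three LASSO models (ratios only / ratios + risk factors
   with a BMI×menopause interaction / risk factors only), compared by
   paired DeLong tests, with Youden-index cut-offs; a 77-SNP polygenic risk
   score `PRS = Σ_k log(OR_k) · dosage_k` is computed from genotype dosages.

## Worked example

The `analysis/` drivers run the whole study flow on a simulated cohort
(65 cases / 66 controls, 50 miRs, 5 truly differential ratio pairs):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_discovery.R
Rscript analysis/03_qpcr_validation.R
Rscript analysis/04_combined_models.R
```

Stage 2 prints the discovery funnel and recovery of the injected truth:

```
 $ input_mirs   :52
 $ filtered_mirs:50
 $ unique_mirs  :48
 $ n_ratios     :1128
 $ n_strategy1  :215
 $ n_strategy2  :98
injected differential ratios recovered in the union: 5 of 5
```

52 miR rows (50 miRs, two duplicated at a second locus) pass the mean>20
filter as 50, collapse to 48 unique profiles and give 48·47/2 = 1128
ratios. The injected log2 effect of 1.5 is strong, so screening keeps many
correlated ratios and the cross-validated AUC is near 1; the synthetic
signal is deliberately clearer than real plasma data (see the methods
vignette). Stage 4 compares the three models:

```
ratios        AUC 1.000 (1.000-1.000) | cutoff 0.496 sens 100.0% spec 100.0%
nonmolecular  AUC 0.684 (0.595-0.773) | cutoff 0.528 sens 52.3% spec 78.8%
   ratios nonmolecular    1 0.684 6.94 3.94e-12
```

i.e. the covariate-only model sits at AUC 0.68 while adding ratio features
is a significant improvement (paired DeLong Z = 6.94).

Interactively, the same stages are plain function calls:

```r
library(miRatio)
cm  <- read_count_matrix("counts.tsv", "labels.tsv")
d   <- run_discovery(cm, discovery_config(seed = 1))
d$union                     # screened ratio ids
d$cv$strategy1$mean         # cross-validated performance
qc_triplicate(c(28, 29, NA))$ct_mean   # -> 28.5 (ND -> 40, then trimmed)
```

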