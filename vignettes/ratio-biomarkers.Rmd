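---
title: "Normalization-free miRNA ratio biomarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization-free miRNA ratio biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRatio)
```

## Why ratios

Plasma small-RNA sequencing counts are proportional to an unknown
per-sample factor (library size, plasma input, extraction efficiency), and
RT-qPCR quantification conventionally divides by a normalizer gene whose
own stability must be assumed. Both problems disappear if the feature is
the ratio of two miRs measured *within* the same sample: any per-sample
multiplicative factor cancels exactly. The cost is combinatorial — `n`
retained miRs give `n(n-1)/2` candidate ratios — which is why the pipeline
couples ratio construction with aggressive screening and a sparse model.

On the sequencing arm a ratio is `(c_i + 1)/(c_j + 1)` on raw counts; on
the qPCR arm the same quantity is measured as
`ΔCt = Ct_mean(denominator) − Ct_mean(numerator)`, which under ideal
amplification efficiency equals the log2 abundance ratio. Sequencing
ratios are therefore log2-transformed wherever the two platforms are
compared or modelled together.

## The discovery model, stage by stage

**Count filter.** A miR is retained when its across-sample mean raw count
is strictly greater than `min_mean = 20`. The strict inequality matters
only for integer boundary cases but is asserted by tests.

**Profile deduplication.** Clustered loci, or one mature sequence under
two annotation names, produce miR rows with *identical* count vectors.
Each group collapses to one row under a merged id (`"a|b"`), and the alias
map is kept so the qPCR mapping stage can resolve merged ids to a mature
miR. Identity is exact vector equality by default; a `tolerance` argument
exists for near-identical profiles but is deliberately off (0) — the one
near-identical pair known from practice is handled by an explicit
manual-exclusion list at the assay-mapping step, not inferred.

**Ratio orientation.** Unordered pairs are canonicalised with the
lexicographically smaller miR id as numerator. Orientation is a pure
convention: flipping a pair inverts the values pointwise and maps the fold
change FC to 1/FC, and both selection gates are symmetric (FC > 2 *or*
< 0.5), so selection is orientation-invariant (tested).

**Pseudocount.** The mean>20 filter makes zero counts rare but not
impossible, so 1 is added to numerator and denominator. On zero-free data
this leaves the Mann–Whitney U of the test fixture unchanged; it is *not*
a theorem for arbitrary data — `(x+c)/(y+c)` can reorder two samples when
counts are small relative to the pseudocount — which is one reason the
screening threshold sits at a mean of 20, where the perturbation is
negligible.

**Screening.** Each ratio is tested with a two-sided Mann–Whitney U test
(normal approximation with tie and continuity correction at cohort sizes;
the scalar `mann_whitney()` switches to the exact distribution for 12 or
fewer tie-free observations) and corrected by Benjamini–Hochberg.
Strategy 1 requires adjusted p ≤ 0.01 and FC > 2 or < 0.5; strategy 2
requires adjusted p ≤ 0.01 and a control coefficient of variation < 0.5 —
the same significance definition, two different stability notions. Both
thresholds are exposed in `discovery_config()` with the stated defaults.

**Sparse signature.** The LASSO logistic model is fitted on standardized
log2 ratios (L1 penalties are scale-sensitive; log2 puts sequencing ratios
on the ΔCt scale). The penalty is chosen by stratified cross-validated
binomial deviance; the deviance-minimising `lambda.min` is the default
rule, with `"1se"` exposed as the parsimonious alternative. The two rules
differ in character: `lambda.min` accepts a few noise features in exchange
for predictive risk, while `1se` keeps at most about one noise feature in
over 90% of pure-noise simulations — the package's parsimony tests use
`1se` for exactly that reason. Coefficients are reported on the
unstandardized (log2) scale, and features with zero coefficient are
reported as unselected.

## Performance assessment

Cross-validation is stratified by outcome, seeded, and — critically —
re-runs the *entire screening* inside every training fold. Screening on
the full data before CV leaks selection optimism into the folds; the
package's null-control property (below) would fail under that design. A
fold whose screening returns nothing falls back to the training
prevalence, contributing an AUC of 0.5 and an undefined (NA) calibration
slope.

Four held-out metrics are reported:

- **calibration intercept** — intercept of
  `logit P(y=1) = a + logit(p̂)` with slope fixed at 1 (ideal 0);
- **calibration slope** — slope of `logit P(y=1) = a + b·logit(p̂)`
  (ideal 1; `b < 1` means predictions too extreme);
- **scaled Brier score** — Brier score divided by the Brier score of the
  constant-prevalence predictor, so 0 is perfect and 1 is uninformative.
  This orientation (rather than the complementary index of prediction
  accuracy, `1 −` the same quantity, exposed as `type = "ipa"`) was chosen
  so that "closer to zero is better" holds for intercept and Brier alike;
- **AUC** — rank-based with ties counted one half; identical to
  `U/(n1·n0)` (asserted against the rank-sum machinery), with DeLong
  confidence intervals and paired DeLong model comparisons via pROC.

The Youden cut-off maximises sensitivity + specificity − 1 over midpoints
between adjacent sorted unique predictions; ties are broken toward the
larger cut-off (higher specificity), a convention that matters only on
small validation sets.

Univariate odds ratios use plain logistic regression with Wald intervals,
so a 2×2 exposure reproduces the cross-product ratio exactly; ordinal
exposures get the Cochran–Armitage trend test with equally spaced scores.
Zero cells and separation are reported in a `note` column, never silently
corrected.

## The RT-qPCR arm

Triplicate QC follows the stated rule in a single pass: non-detects are
imputed to Ct 40 first, then any replicate lying strictly more than one
sample standard deviation from the triplicate mean is removed and the mean
recomputed. Two consequences deserve documentation:

1. **At most one replicate can ever be removed.** For three deviations
   summing to zero, the extreme one satisfies `|d_max| = |d_2| + |d_3|`,
   and the squared deviations sum to twice the variance, so two deviations
   cannot both exceed one sd. The tests assert this over 10⁵ random
   triplicates.
2. **For distinct replicates the rule almost always fires.** From the same
   identity, `|d_max| > s` is equivalent to `d_2·d_3 > 0`, which holds for
   every triplicate except when the middle replicate equals the mean
   exactly (e.g. the arithmetic progression {24.1, 24.2, 24.3}, which is
   retained — the comparison carries a 1e-9 tolerance so floating-point
   noise cannot break the boundary case). The rule is therefore best
   understood as "trim the farthest replicate", and a genuine outlier is
   what gets trimmed when one exists. It is implemented exactly as stated;
   the synthetic tests assert the provable behaviour rather than a naive
   exclusion count.

Duplicates (two replicates) skip the trimming rule — with two points each
deviation equals the sd, so the rule would always fire — and are flagged.
Whether "one standard deviation" means the sample (n−1) or population sd
is not specified anywhere authoritative; the sample sd was chosen, and the
choice moves the boundary only marginally.

Assay mapping collapses locus-suffixed ids (`let-7f-5p-2` → `let-7f-5p`)
because different genomic loci share one mature sequence, deduplicates
ratios that become identical after collapse, and then applies the explicit
manual-exclusion list. Cross-platform concordance is the per-ratio
Spearman correlation between log2 sequencing ratios and ΔCt values
(Spearman is invariant to the monotone log, so the flag does not depend on
the transform), with the concordant flag at p < 0.01 and rho > 0.

## The synthetic cohort generator

`generator_config()` encodes the study conditions: 65 cases / 66 controls;
50 miRs with log-normal baseline means (log-mean `log 150`, log-sd 1.2, so
a realistic minority falls below the mean-20 filter); negative-binomial
counts with dispersion 0.1 (typical small-RNA-seq overdispersion);
log-normal library-size factors (log-sd 0.5) that cancel in every ratio;
5 differential pairs injected by shifting the numerator miR by 1.5 log2
units in cases only — creating true *ratio* effects while marginal count
distributions stay realistic; two miRs duplicated as exact two-locus
copies; a linear Ct model (intercept 36, slope 1 = ideal efficiency, noise
sd 0.25, censoring at Ct 40) sharing the latent abundance layer with the
counts; screening-cohort covariates with a logistic outcome model including
the BMI-class×menopause interaction; and 77 Hardy–Weinberg SNPs for the
PRS. All draws derive from one mandatory seed; the same seed gives a
bit-identical cohort.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: hemolysis and other pre-analytic artefacts,
batch effects beyond library size, correlated miR co-regulation (counts
are independent across miRs given the latent layer), amplification-
efficiency differences between assays, and genuinely weak effect sizes.
The injected 1.5-log2 effect is deliberately strong (it is the condition
under which every injected ratio should reach adjusted p ≤ 0.01 at
n = 200/200), so the demonstration cohort separates almost perfectly —
real plasma signatures do not.

## Problem sizes used by the tests

The suite verifies the statistical machinery against independent oracles
(exhaustive Mann–Whitney enumeration for ≤ 10 observations, a
10,000-resample bootstrap z for the DeLong comparison, the hand
chi-square trend formula) and the pipeline against known truth: a 50-seed
null control at 65/66 samples (mean within-fold-selection CV AUC must stay
within 0.43–0.57) and a 25-seed recovery run at 300/300 samples (at least
4 of 5 injected ratios in the strategy union in at least 80% of seeds).
These sizes keep the full suite and the acceptance script each around
three minutes on one CPU while leaving the binomial noise on every
asserted proportion well inside its tolerance.

## Known limitations

- The penalty rule, fold assignment and seed conventions are explicit
  config, but no attempt is made to reproduce any particular published
  signature — with `n(n-1)/2` highly correlated candidates the selected
  ratio set is intrinsically unstable at cohort sizes of ~130.
- Calibration metrics on 26-sample held-out folds are noisy; fold-wise
  values are retained alongside the means for exactly that reason.
- Missing genotypes contribute zero to the PRS by default (count
  reported); mean-dosage imputation (`2·af`) is available but off.
- Complete-case handling for the combined model drops rows with any
  missing covariate and logs the count; no imputation is attempted.
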