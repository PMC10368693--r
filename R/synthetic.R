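#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: a nested
#' case-control series of 65 cases / 66 controls, negative-binomial
#' small-RNA-seq counts with log-normal per-sample library-size factors,
#' a handful of truly differential miR *ratios* injected by shifting the
#' numerator miR in cases only, exact duplicate count profiles (same
#' mature miR annotated at two loci), an ideal-efficiency Ct model for
#' the qPCR arm, screening-cohort covariates with a logistic outcome model
#' including a BMI-by-menopause interaction, and Hardy-Weinberg SNP
#' dosages for a 77-SNP risk panel.
#'
#' @param seed integer seed (mandatory; every draw is derived from it).
#' @param n_cases,n_controls sample sizes.
#' @param n_mirs number of simulated miRs (before duplicates).
#' @param n_differential number of truly differential miR pairs.
#' @param effect_size log2 shift of each differential pair's numerator
#'   miR in cases.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_sd sd of per-sample log library-size factors.
#' @param n_duplicate_pairs miRs duplicated as exact two-locus copies.
#' @param base_log_mean,base_log_sd log-normal parameters of per-miR
#'   baseline mean counts.
#' @param ct_intercept,ct_slope,ct_noise_sd Ct model
#'   `Ct = intercept - slope * log2(concentration) + N(0, noise_sd)`.
#' @param nondetect_ct censoring threshold: replicate Cts at or above it
#'   become non-detects (default 40).
#' @param outlier_rate fraction of triplicates receiving one shifted
#'   outlier replicate.
#' @param outlier_shift Ct shift added to an outlier replicate.
#' @param logor_bmi30,logor_menopause,logor_interaction,logor_wcrf,logor_tabar,logor_prs
#'   outcome-model log odds ratios (BMI>=30 indicator, menopause
#'   indicator, their product, per WCRF unit, per Tabar class step, per
#'   PRS unit).
#' @param n_snps panel size (default 77).
#' @param maf_range allele-frequency range for SNPs.
#' @param genotype_missing_rate per-genotype missingness.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_cases = 65, n_controls = 66,
                             n_mirs = 50, n_differential = 5,
                             effect_size = 1.5, dispersion = 0.1,
                             libsize_sd = 0.5, n_duplicate_pairs = 2,
                             base_log_mean = log(150), base_log_sd = 1.2,
                             ct_intercept = 36, ct_slope = 1,
                             ct_noise_sd = 0.25, nondetect_ct = 40,
                             outlier_rate = 0.05, outlier_shift = 4,
                             logor_bmi30 = 0.7, logor_menopause = 0.2,
                             logor_interaction = 0.3, logor_wcrf = -0.38,
                             logor_tabar = 0.48, logor_prs = 0.1,
                             n_snps = 77, maf_range = c(0.1, 0.5),
                             genotype_missing_rate = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$n_cases > 0, cfg$n_controls > 0, cfg$n_mirs >= 2,
            cfg$n_differential >= 0, cfg$dispersion > 0,
            2 * cfg$n_differential <= cfg$n_mirs)
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic miR count matrix with known differential ratios
#'
#' Counts are negative-binomial around `base_mean * library_factor`,
#' with each differential pair's numerator mean multiplied by
#' `2^effect_size` in cases only — so the truth lives in ratios while
#' per-sample library size (which cancels in every ratio) varies freely.
#' Duplicate-profile miRs are exact row copies carrying two-locus ids
#' (`<mir>-1` / `<mir>-2`).
#'
#' @param cfg a [generator_config()].
#' @return list with `cm` (a [count_matrix()]), `latent`
#'   (noise-free mean concentrations, miRs x samples, duplicate rows
#'   included), `lib` (library-size factors) and `truth` (list:
#'   `differential_ratios` canonical ratio ids, `differential_pairs`
#'   data.frame, `effect_size`, `duplicates` named vector
#'   original -> duplicated id).
#' @export
generate_counts <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls
  sample_ids <- c(sprintf("case_%03d", seq_len(cfg$n_cases)),
                  sprintf("ctrl_%03d", seq_len(cfg$n_controls)))
  labels <- stats::setNames(rep(c("case", "control"),
                                c(cfg$n_cases, cfg$n_controls)), sample_ids)
  mir_ids <- sprintf("miR-%03d-5p", seq_len(cfg$n_mirs))
  base <- stats::rlnorm(cfg$n_mirs, cfg$base_log_mean, cfg$base_log_sd)
  names(base) <- mir_ids

  # differential pairs among well-expressed miRs so the mean filter
  # retains them
  truth_pairs <- NULL
  diff_ids <- character(0)
  if (cfg$n_differential > 0) {
    eligible <- names(base)[base > 40]
    if (length(eligible) < 2 * cfg$n_differential) {
      top_up <- names(sort(base, decreasing = TRUE))
      eligible <- unique(c(eligible, top_up))[seq_len(2 * cfg$n_differential)]
      base[eligible] <- pmax(base[eligible], 50)
    }
    picked <- sample(eligible, 2 * cfg$n_differential)
    num <- picked[seq_len(cfg$n_differential)]
    den <- picked[cfg$n_differential + seq_len(cfg$n_differential)]
    truth_pairs <- data.frame(numerator = num, denominator = den,
                              ratio_id = canonical_ratio_id(num, den),
                              stringsAsFactors = FALSE)
    diff_ids <- num
  }

  lib <- exp(stats::rnorm(n, 0, cfg$libsize_sd))
  mu <- outer(base, lib)
  dimnames(mu) <- list(mir_ids, sample_ids)
  if (length(diff_ids) > 0) {
    is_case <- labels == "case"
    mu[diff_ids, is_case] <- mu[diff_ids, is_case] * 2^cfg$effect_size
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  dup_map <- stats::setNames(character(0), character(0))
  if (cfg$n_duplicate_pairs > 0) {
    non_diff <- setdiff(mir_ids, c(truth_pairs$numerator,
                                   truth_pairs$denominator))
    dup_src <- sample(non_diff, min(cfg$n_duplicate_pairs, length(non_diff)))
    for (id in dup_src) {
      id1 <- paste0(id, "-1"); id2 <- paste0(id, "-2")
      i <- match(id, rownames(counts))
      rownames(counts)[i] <- id1
      rownames(mu)[i] <- id1
      counts <- rbind(counts, counts[id1, , drop = FALSE])
      mu <- rbind(mu, mu[id1, , drop = FALSE])
      rownames(counts)[nrow(counts)] <- id2
      rownames(mu)[nrow(mu)] <- id2
      dup_map[id1] <- id2
    }
  }

  list(cm = count_matrix(counts, labels),
       latent = mu, lib = lib,
       truth = list(differential_ratios = truth_pairs$ratio_id,
                    differential_pairs = truth_pairs,
                    effect_size = cfg$effect_size,
                    duplicates = dup_map))
}

#' Generate RT-qPCR triplicate plates from latent concentrations
#'
#' Shares the latent abundance layer of [generate_counts()]: each
#' replicate draws `Ct = intercept - slope * log2(concentration) +`
#' Gaussian noise. A configured fraction of triplicates receives one
#' outlier replicate (shifted by `outlier_shift`); replicates at or
#' above `nondetect_ct` are censored to non-detects (`NA`).
#'
#' @param cfg a [generator_config()].
#' @param concentrations matrix (assays x samples) of positive latent
#'   concentrations; rownames are assay ids.
#' @param n_replicates replicates per (sample, assay) (default 3).
#' @return long-format data.frame (`sample_id`, `assay_id`,
#'   `replicate`, `ct`, `nondetect`) as from [read_ct_plates()].
#' @export
generate_ct_plates <- function(cfg, concentrations, n_replicates = 3) {
  set.seed(cfg$seed + 1L)
  assays <- rownames(concentrations)
  samples <- colnames(concentrations)
  na <- length(assays); ns <- length(samples)
  grid <- expand.grid(assay = seq_len(na), sample = seq_len(ns))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    i <- grid$assay[g]; j <- grid$sample[g]
    mu_ct <- cfg$ct_intercept -
      cfg$ct_slope * log2(concentrations[i, j])
    ct <- mu_ct + stats::rnorm(n_replicates, 0, cfg$ct_noise_sd)
    if (cfg$outlier_rate > 0 &&
        stats::runif(1) < cfg$outlier_rate) {
      k <- sample.int(n_replicates, 1)
      ct[k] <- ct[k] + cfg$outlier_shift
    }
    nd <- ct >= cfg$nondetect_ct
    ct[nd] <- NA_real_
    rows[[g]] <- data.frame(sample_id = samples[j], assay_id = assays[i],
                            replicate = seq_len(n_replicates), ct = ct,
                            nondetect = nd, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic covariate / genotype cohort
#'
#' Covariates are drawn from plausible screening-population marginals
#' (BMI, menopause, WCRF lifestyle score, Tabar and BI-RADS density
#' classes), SNP dosages from Hardy-Weinberg equilibrium at uniform
#' allele frequencies, and the PRS from synthetic panel weights. Labels
#' are drawn from a logistic outcome model with the configured log odds
#' ratios (including the BMI-class-by-menopause interaction); cases and
#' controls are then sampled from the pool to the configured sizes.
#'
#' @param cfg a [generator_config()].
#' @return list with `cohort` (data.frame: `sample_id`, `label`, `bmi`,
#'   `bmi30`, `menopause`, `wcrf`, `tabar`, `birads`, `prs`,
#'   `n_missing_snp`), `genotypes` (samples x SNPs dosage matrix with
#'   `NA` missing), `weights` (named log-OR vector), `af` (allele
#'   frequencies), `truth` (configured log odds ratios).
#' @export
generate_cohort_covariates <- function(cfg) {
  set.seed(cfg$seed + 2L)
  n_target <- cfg$n_cases + cfg$n_controls
  pool <- 60 * n_target
  bmi <- pmax(15, stats::rnorm(pool, 26.8, 5.7))
  bmi30 <- as.numeric(bmi >= 30)
  men <- stats::rbinom(pool, 1, 0.81)
  wcrf <- pmin(7, pmax(0, stats::rnorm(pool, 5.3, 1.05)))
  tabar <- sample(1:4, pool, replace = TRUE, prob = c(.25, .37, .10, .28))
  birads <- sample(1:3, pool, replace = TRUE, prob = c(.32, .47, .21))
  af <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  snp_ids <- sprintf("rs%05d", seq_len(cfg$n_snps))
  names(af) <- snp_ids
  weights <- stats::setNames(stats::rnorm(cfg$n_snps, 0.05, 0.05), snp_ids)
  geno <- matrix(stats::rbinom(pool * cfg$n_snps, 2, rep(af, each = pool)),
                 nrow = pool, dimnames = list(NULL, snp_ids))
  if (cfg$genotype_missing_rate > 0) {
    miss <- stats::runif(length(geno)) < cfg$genotype_missing_rate
    geno[miss] <- NA
  }
  rownames(geno) <- sprintf("pool_%05d", seq_len(pool))
  prs <- compute_prs(geno, weights)
  eta <- -1.5 +
    cfg$logor_bmi30 * bmi30 +
    cfg$logor_menopause * men +
    cfg$logor_interaction * bmi30 * men +
    cfg$logor_wcrf * (wcrf - 5.3) +
    cfg$logor_tabar * (tabar - 1) +
    cfg$logor_prs * (prs$prs - mean(prs$prs))
  y <- stats::rbinom(pool, 1, stats::plogis(eta))
  if (sum(y == 1) < cfg$n_cases || sum(y == 0) < cfg$n_controls)
    stop("pool too small for requested case/control counts")
  idx <- c(sample(which(y == 1), cfg$n_cases),
           sample(which(y == 0), cfg$n_controls))
  sample_ids <- c(sprintf("case_%03d", seq_len(cfg$n_cases)),
                  sprintf("ctrl_%03d", seq_len(cfg$n_controls)))
  cohort <- data.frame(
    sample_id = sample_ids,
    label = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
    bmi = bmi[idx], bmi30 = bmi30[idx], menopause = men[idx],
    wcrf = wcrf[idx], tabar = tabar[idx], birads = birads[idx],
    prs = prs$prs[idx], n_missing_snp = prs$n_missing[idx],
    stringsAsFactors = FALSE)
  genotypes <- geno[idx, , drop = FALSE]
  rownames(genotypes) <- sample_ids
  list(cohort = cohort, genotypes = genotypes, weights = weights, af = af,
       truth = list(logor_bmi30 = cfg$logor_bmi30,
                    logor_menopause = cfg$logor_menopause,
                    logor_interaction = cfg$logor_interaction,
                    logor_wcrf = cfg$logor_wcrf,
                    logor_tabar = cfg$logor_tabar,
                    logor_prs = cfg$logor_prs))
}

# collapse latent per-locus concentrations to mature-miR assay
# concentrations (duplicate loci share one mature sequence, so one row)
mature_concentrations <- function(latent) {
  mature <- collapse_locus(rownames(latent))
  keep <- !duplicated(mature)
  out <- latent[keep, , drop = FALSE]
  rownames(out) <- mature[keep]
  out
}

#' Simulate and write a complete synthetic cohort
#'
#' Runs all three generators with a shared latent layer and writes
#' every pipeline input as plain TSV plus a ground-truth JSON for
#' parameter-recovery tests: `counts.tsv`, `labels.tsv`,
#' `ct_plates.tsv` (all mature-miR assays), `covariates.tsv`,
#' `genotypes.tsv`, `snp_weights.tsv`, `latent_concentrations.tsv`,
#' `truth.json`.
#'
#' @param cfg a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the in-memory objects: `cm`, `plates`,
#'   `covariates`, `truth`, and the written `paths`.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- generate_counts(cfg)
  conc <- mature_concentrations(g$latent)
  plates <- generate_ct_plates(cfg, conc)
  cov <- generate_cohort_covariates(cfg)

  p <- function(f) file.path(out_dir, f)
  write_count_matrix(g$cm, p("counts.tsv"), p("labels.tsv"))
  write_ct_plates(plates, p("ct_plates.tsv"))
  utils::write.table(cov$cohort, p("covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  geno_df <- data.frame(sample_id = rownames(cov$genotypes),
                        cov$genotypes, check.names = FALSE)
  utils::write.table(geno_df, p("genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(snp_id = names(cov$weights), log_or = unname(cov$weights),
               af = unname(cov$af)),
    p("snp_weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  conc_df <- data.frame(assay_id = rownames(conc), conc, check.names = FALSE)
  utils::write.table(conc_df, p("latent_concentrations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- c(g$truth, cov["truth"])
  write_metrics_json(truth, p("truth.json"))

  invisible(list(cm = g$cm, latent = g$latent, plates = plates,
                 covariates = cov, truth = g$truth,
                 paths = vapply(c("counts.tsv", "labels.tsv", "ct_plates.tsv",
                                  "covariates.tsv", "genotypes.tsv",
                                  "snp_weights.tsv",
                                  "latent_concentrations.tsv", "truth.json"),
                                p, character(1))))
}
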