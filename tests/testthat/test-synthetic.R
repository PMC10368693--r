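test_that("same seed gives a bit-identical cohort; ratios ignore library size", {
  cfg <- generator_config(seed = 77)
  g1 <- generate_counts(cfg)
  g2 <- generate_counts(cfg)
  expect_identical(g1$cm$counts, g2$cm$counts)
  expect_identical(g1$truth, g2$truth)
  p1 <- generate_ct_plates(cfg, mature_conc <- miRatio:::mature_concentrations(g1$latent))
  p2 <- generate_ct_plates(cfg, mature_conc)
  expect_identical(p1, p2)
  c1 <- generate_cohort_covariates(cfg)
  expect_identical(c1, generate_cohort_covariates(cfg))

  # multiplying a sample's counts by a constant leaves ratios unchanged
  # up to the pseudocount; with pseudocount 0 the invariance is exact
  cm <- g1$cm
  scaled <- cm$counts
  scaled[, 3] <- scaled[, 3] * 7
  rm1 <- build_ratio_matrix(cm, pseudocount = 0)
  rm2 <- build_ratio_matrix(count_matrix(scaled, cm$labels), pseudocount = 0)
  ok <- is.finite(rm1$values[, 3]) & is.finite(rm2$values[, 3]) &
    !is.nan(rm1$values[, 3]) & !is.nan(rm2$values[, 3])
  expect_equal(rm1$values[ok, 3], rm2$values[ok, 3])
})

test_that("injected duplicate profiles are recovered exactly", {
  g <- generate_counts(generator_config(seed = 5, n_duplicate_pairs = 3))
  dd <- deduplicate_profiles(filter_mirs(g$cm))
  retained_dups <- g$truth$duplicates[
    paste0(names(g$truth$duplicates)) %in%
      rownames(filter_mirs(g$cm)$counts)]
  for (orig in names(retained_dups)) {
    merged <- grep(orig, dd$cm$mir_ids, fixed = TRUE, value = TRUE)
    expect_length(merged, 1)
    expect_match(merged, "|", fixed = TRUE)
  }
})

test_that("the Ct model is exact at zero noise and censors non-detects", {
  cfg <- generator_config(seed = 9, ct_noise_sd = 0, outlier_rate = 0)
  conc <- matrix(c(64, 256, 32, 128), nrow = 2,
                 dimnames = list(c("mA", "mB"), c("s1", "s2")))
  plates <- generate_ct_plates(cfg, conc)
  ctm <- qc_ct_plates(plates)
  wide <- with(ctm, tapply(ct_mean, list(assay_id, sample_id), identity))
  # delta Ct recovers log2 concentration ratios exactly
  for (s in c("s1", "s2")) {
    expect_equal(delta_ct_ratio(wide["mA", s], wide["mB", s]),
                 log2(conc["mA", s] / conc["mB", s]))
  }

  # very low concentration -> Ct above 40 -> non-detect
  weak <- matrix(c(0.001, 100), 2, 1, dimnames = list(c("lo", "hi"), "s1"))
  pl <- generate_ct_plates(cfg, weak)
  expect_true(all(pl$nondetect[pl$assay_id == "lo"]))
  expect_false(any(pl$nondetect[pl$assay_id == "hi"]))
})

test_that("triplicate trimming removes the extreme replicate, outliers first", {
  # for three distinct replicates the extreme deviation always exceeds
  # one sd (deviations sum to zero, so |d_max| = |d2| + |d3| and
  # |d_max| > sd iff d2*d3 > 0): the rule trims the farthest replicate
  # of essentially every noisy triplicate
  cfg <- generator_config(seed = 13, outlier_rate = 0.1, n_mirs = 20,
                          ct_noise_sd = 0.2)
  g <- generate_counts(cfg)
  plates <- generate_ct_plates(cfg, miRatio:::mature_concentrations(g$latent))
  ctm <- qc_ct_plates(plates)
  triplets <- ctm[ctm$n_replicates == 3 & ctm$n_nondetect == 0, ]
  expect_gt(mean(triplets$n_excluded), 0.95)
  expect_lte(max(triplets$n_excluded), 1)

  # an injected outlier (+4 Ct against 0.2 noise) is the trimmed
  # replicate, so the post-QC mean shifts by < 0.5 Ct
  base <- 30 + rnorm(3, 0, 0.2)
  shifted <- base; shifted[2] <- shifted[2] + 4
  q <- qc_triplicate(shifted)
  expect_equal(q$excluded, 2L)
  expect_lt(abs(q$ct_mean - mean(base[-2])), 1e-9)
})

test_that("cohort covariates honour their configured effect sizes", {
  # null generator: covariate ORs compatible with 1
  cfg0 <- generator_config(seed = 21, n_cases = 600, n_controls = 600,
                           logor_bmi30 = 0, logor_menopause = 0,
                           logor_interaction = 0, logor_wcrf = 0,
                           logor_tabar = 0, logor_prs = 0)
  cov0 <- generate_cohort_covariates(cfg0)
  y0 <- label01(cov0$cohort$label)
  or_b <- univariate_or(cov0$cohort$bmi30, y0, reference = "0")
  expect_true(or_b$ci_low < 1 && 1 < or_b$ci_high)
  expect_gt(cochran_armitage(cov0$cohort$tabar, y0), 0.01)

  # configured log-OR recovered by an unpenalised fit at n = 5000
  cfg1 <- generator_config(seed = 22, n_cases = 2500, n_controls = 2500,
                           logor_bmi30 = 0.7, logor_menopause = 0,
                           logor_interaction = 0, logor_wcrf = 0,
                           logor_tabar = 0, logor_prs = 0)
  cov1 <- generate_cohort_covariates(cfg1)
  fit <- glm(label01(cov1$cohort$label) ~ cov1$cohort$bmi30,
             family = binomial())
  expect_equal(unname(coef(fit)[2]), 0.7, tolerance = 0.15)

  # Tabar trend is detected when injected
  cfg2 <- generator_config(seed = 23, n_cases = 200, n_controls = 200,
                           logor_bmi30 = 0, logor_menopause = 0,
                           logor_interaction = 0, logor_wcrf = 0,
                           logor_tabar = 0.5, logor_prs = 0)
  hits <- vapply(1:10, function(s) {
    cfg <- generator_config(seed = 3000 + s, n_cases = 200, n_controls = 200,
                            logor_bmi30 = 0, logor_menopause = 0,
                            logor_interaction = 0, logor_wcrf = 0,
                            logor_tabar = 0.5, logor_prs = 0)
    cc <- generate_cohort_covariates(cfg)
    cochran_armitage(cc$cohort$tabar, label01(cc$cohort$label)) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # Hardy-Weinberg dosages and PRS present for every sample
  expect_true(all(cov0$genotypes %in% c(0, 1, 2) | is.na(cov0$genotypes)))
  expect_equal(nrow(cov0$cohort), 1200)
})

test_that("simulate_cohort writes a readable, consistent file set", {
  tmp <- withr::local_tempdir()
  sim <- simulate_cohort(generator_config(seed = 31, n_mirs = 12,
                                          n_differential = 2,
                                          n_duplicate_pairs = 1), tmp)
  cm <- read_count_matrix(file.path(tmp, "counts.tsv"),
                          file.path(tmp, "labels.tsv"))
  expect_identical(cm$counts, sim$cm$counts)
  plates <- read_ct_plates(file.path(tmp, "ct_plates.tsv"))
  expect_equal(sort(unique(plates$sample_id)), sort(cm$sample_ids))
  truth <- jsonlite::read_json(file.path(tmp, "truth.json"))
  expect_length(unlist(truth$differential_ratios), 2)
  w <- read_panel_weights(file.path(tmp, "snp_weights.tsv"))
  expect_length(w, 77)
})
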