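test_that("AUC equals the rank-sum identity and respects symmetry", {
  set.seed(1)
  y <- rep(c(1, 0), c(12, 15))
  p <- rnorm(27)
  mw <- mann_whitney(p[y == 1], p[y == 0])
  expect_equal(auc(p, y), mw$U / (12 * 15))
  expect_equal(auc(p, y) + auc(-p, y), 1)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 10), rep(c(1, 0), 5)), 0.5)
  # ties counted one half
  expect_equal(auc(c(1, 1, 0), c(1, 0, 0)), 0.75)
  ci <- auc_ci(p, y)
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
})

test_that("calibration intercept and slope recover known miscalibrations", {
  set.seed(2)
  n <- 5000
  p <- plogis(rnorm(n, -0.5, 1.2))
  y <- rbinom(n, 1, p)
  # correctly specified: intercept ~ 0, slope ~ 1
  expect_lt(abs(calibration_intercept(p, y)), 0.1)
  expect_lt(abs(calibration_slope(p, y) - 1), 0.1)

  # odds uniformly halved -> intercept ~ log 2
  p_half <- plogis(qlogis(p) - log(2))
  expect_equal(calibration_intercept(p_half, y), log(2), tolerance = 0.12)

  # logits doubled before the sigmoid -> slope ~ 0.5 (too extreme)
  p_wide <- plogis(2 * qlogis(p))
  expect_equal(calibration_slope(p_wide, y), 0.5, tolerance = 0.07)

  # constant prediction at the prevalence: intercept 0, slope undefined
  pc <- rep(mean(y), n)
  expect_equal(calibration_intercept(pc, y), 0, tolerance = 1e-6)
  expect_error(calibration_slope(pc, y), "constant")

  # self-consistency: refit probabilities of a logistic model give (0, 1)
  x <- rnorm(500)
  yy <- rbinom(500, 1, plogis(x))
  ph <- fitted(glm(yy ~ x, family = binomial()))
  expect_equal(calibration_intercept(ph, yy), 0, tolerance = 1e-6)
  expect_equal(calibration_slope(ph, yy), 1, tolerance = 1e-6)
})

test_that("scaled Brier score matches direct arithmetic and its anchors", {
  y <- c(1, 1, 0, 0)
  expect_equal(scaled_brier(c(0.8, 0.6, 0.3, 0.1), y), 0.075 / 0.25)
  expect_equal(scaled_brier(y, y), 0)                       # perfect
  expect_equal(scaled_brier(rep(0.5, 4), y), 1)             # null model
  expect_equal(scaled_brier(c(0.8, 0.6, 0.3, 0.1), y, type = "ipa"),
               1 - 0.3)
  expect_error(scaled_brier(rep(0.2, 3), c(1, 1, 1)), "both classes")
})

test_that("DeLong paired test: identity, power, bootstrap agreement", {
  set.seed(3)
  n <- 300
  y <- rep(c(1, 0), c(150, 150))
  p1 <- plogis(1.2 * y + rnorm(n))
  expect_equal(delong_paired_test(p1, p1, y)$p, 1)
  expect_equal(delong_paired_test(p1, p1, y)$Z, 0)

  # informative vs pure-noise predictor: significant in most seeds
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    y <- rep(c(1, 0), each = 250)
    good <- y + rnorm(500)
    noise <- rnorm(500)
    delong_paired_test(good, noise, y)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # Z within 15% of a bootstrap z on a fixed synthetic set
  set.seed(5)
  y <- rep(c(1, 0), each = 75)
  s1 <- y * 0.9 + rnorm(150)
  s2 <- y * 0.3 + rnorm(150)
  z_dl <- delong_paired_test(s1, s2, y)$Z
  z_bs <- bootstrap_auc_diff_z(s1, s2, y, B = 4000, seed = 9)
  expect_equal(abs(z_dl), abs(z_bs), tolerance = 0.15 * abs(z_bs))
})

test_that("Youden cut-off maximises J with ties broken upward", {
  r <- youden_cutoff(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 0.4 && r$cutoff <= 0.8)

  # exhaustive check on a small overlapping set
  p <- c(0.1, 0.3, 0.35, 0.5, 0.7, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  r2 <- youden_cutoff(p, y)
  js <- vapply(seq(0, 1, by = 0.001), function(ct) {
    sum(p >= ct & y == 1) / 3 + sum(p < ct & y == 0) / 3 - 1
  }, numeric(1))
  expect_equal(r2$youden, max(js))
  # label-independent scores: J near 0 at large n
  set.seed(6)
  pn <- runif(4000); yn <- rbinom(4000, 1, 0.5)
  expect_lt(youden_cutoff(pn, yn)$youden, 0.1)
})

test_that("univariate ORs equal the cross-product ratio and invert with coding", {
  # previous benign biopsies row: cases 14/49, controls 9/57
  or <- published_or(load_published_counts(), "benign_biopsies", "ge1")
  expect_equal(or$or, (14 * 57) / (9 * 49), tolerance = 1e-6)
  expect_equal(round(or$or, 2), 1.81)
  # the glm route and the closed-form 2x2 helper agree
  cf <- or_from_counts(14, 49, 9, 57)
  expect_equal(or$or, cf$or, tolerance = 1e-6)
  expect_equal(or$ci_low, cf$ci_low, tolerance = 1e-3)

  # symmetric table -> OR 1; swapped coding -> 1/OR
  y <- rep(c(1, 0), each = 20)
  x <- rep(c("a", "b", "a", "b"), each = 10)
  expect_equal(univariate_or(x, y, reference = "a")$or, 1, tolerance = 1e-9)
  or_fw <- published_or(load_published_counts(), "tabar_density", "4or5")$or
  y2 <- rep(c(1, 0, 1, 0), c(25, 13, 10, 22))
  x2 <- rep(c("hi", "ref"), c(38, 32))
  or_bw <- univariate_or(x2, y2, reference = "hi")$or
  expect_equal(or_fw, 1 / or_bw, tolerance = 1e-6)

  # continuous exposure: OR per unit from the logistic slope
  set.seed(7)
  xc <- rnorm(600)
  yc <- rbinom(600, 1, plogis(0.7 * xc))
  oc <- univariate_or(xc, yc, continuous = TRUE)
  expect_equal(log(oc$or), 0.7, tolerance = 0.25)
})

test_that("Cochran-Armitage trend test matches the hand formula and has correct size", {
  # printed toy table oracle
  events <- c(5, 12, 22); totals <- c(40, 40, 40)
  p_pkg <- cochran_armitage(rep(1:3, totals),
                            unlist(mapply(function(e, t) rep(c(1, 0), c(e, t - e)),
                                          events, totals, SIMPLIFY = FALSE)))
  expect_equal(p_pkg, trend_chisq_oracle(events, totals, 1:3),
               tolerance = 1e-12)

  # strong monotone trend detected
  set.seed(8)
  lv <- rep(1:3, each = 100)
  y <- rbinom(300, 1, c(0.1, 0.3, 0.6)[lv])
  expect_lt(cochran_armitage(lv, y), 0.001)

  # null size ~ alpha
  rej <- vapply(1:400, function(s) {
    set.seed(1000 + s)
    y0 <- rbinom(150, 1, 0.3)
    suppressWarnings(cochran_armitage(rep(1:3, each = 50), y0)) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
  expect_error(cochran_armitage(rep(1, 10), rbinom(10, 1, 0.5)), "levels")
})

test_that("cross-validated metrics are seed-deterministic and honest", {
  set.seed(9)
  n <- 600
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, plogis(0.9 * X[, 1] - 0.6 * X[, 2]))
  cv1 <- kfold_cv(X, y, k = 5, seed = 21, cfg = lasso_config(lambda = 0.01))
  cv2 <- kfold_cv(X, y, k = 5, seed = 21, cfg = lasso_config(lambda = 0.01))
  expect_identical(cv1$folds, cv2$folds)
  expect_gt(cv1$mean["auc"], 0.65)
  expect_lt(abs(cv1$mean["calibration_slope"] - 1), 0.35)

  # label-shuffled data: CV AUC hovers at chance
  aucs <- vapply(1:12, function(s) {
    set.seed(500 + s)
    ys <- sample(y)
    kfold_cv(X, ys, k = 5, seed = s,
             cfg = lasso_config(lambda = 0.05))$mean["auc"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("combined model design codes covariates as specified", {
  set.seed(10)
  n <- 300
  ratios <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("r1", "r2")))
  cov <- data.frame(bmi = rnorm(n, 27, 5), menopause = rbinom(n, 1, 0.8),
                    wcrf = rnorm(n, 5, 1), tabar = sample(1:4, n, TRUE))
  y <- rbinom(n, 1, plogis(0.8 * (cov$bmi >= 30) + 0.4 * ratios[, 1]))
  m <- fit_combined_model(ratios, cov, y, lasso_config(lambda = 0.01))
  expect_setequal(m$feature_names,
                  c("r1", "r2", "tabar", "wcrf", "bmi30", "menopause",
                    "bmi30_x_menopause"))
  # full shrinkage reduces to intercept-only
  m0 <- fit_combined_model(ratios, cov, y, lasso_config(lambda = 10))
  expect_length(m0$selected, 0)
  expect_equal(m0$intercept, qlogis(mean(y)), tolerance = 1e-6)

  # injected covariate effect is recovered with high probability
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    cv2 <- data.frame(bmi = rnorm(1000, 27, 5), menopause = rbinom(1000, 1, 0.8),
                      wcrf = rnorm(1000, 5, 1), tabar = sample(1:4, 1000, TRUE))
    r2 <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "r1"))
    y2 <- rbinom(1000, 1, plogis(-0.5 + 1.0 * (cv2$bmi >= 30) + 0.5 * cv2$tabar))
    sel <- fit_combined_model(r2, cv2, y2, lasso_config(seed = s))$selected
    all(c("bmi30", "tabar") %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
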