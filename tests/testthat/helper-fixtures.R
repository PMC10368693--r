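# fixtures and independent oracles used across the suite

# small deterministic count matrix: 4 miRs x 6 samples (3 cases first)
toy_count_matrix <- function() {
  m <- rbind(
    "miR-a" = c(40, 44, 39, 20, 22, 18),
    "miR-b" = c(19, 21, 20, 41, 40, 39),
    "miR-c" = c(100, 110, 95, 102, 99, 101),
    "miR-d" = c(5, 6, 4, 5, 7, 6)
  )
  colnames(m) <- paste0("s", 1:6)
  count_matrix(m, rep(c("case", "control"), each = 3))
}

# exhaustive two-sided Mann-Whitney p by enumerating every assignment
# of the pooled values to the two groups (oracle; no ties assumed)
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# bootstrap z-score for a paired AUC difference (oracle for DeLong)
bootstrap_auc_diff_z <- function(p1, p2, y, B = 2000, seed = 1) {
  set.seed(seed)
  n <- length(y)
  d_obs <- auc(p1, y) - auc(p2, y)
  d_boot <- replicate(B, {
    i <- sample.int(n, replace = TRUE)
    while (length(unique(y[i])) < 2) i <- sample.int(n, replace = TRUE)
    auc(p1[i], y[i]) - auc(p2[i], y[i])
  })
  d_obs / stats::sd(d_boot)
}

# Cochran-Armitage trend chi-square by the explicit textbook formula
trend_chisq_oracle <- function(events, totals, scores) {
  N <- sum(totals); R <- sum(events)
  p_bar <- R / N
  num <- sum(events * scores) - R * sum(totals * scores) / N
  den <- p_bar * (1 - p_bar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  stats::pchisq(num^2 / den, df = 1, lower.tail = FALSE)
}

# published worked-example ORs: expand printed 2x2 counts to
# individual-level data and run the package's logistic route
published_or <- function(counts_df, variable, level) {
  d <- counts_df[counts_df$variable == variable, ]
  ref <- d[d$is_reference == 1, ]
  lev <- d[d$level == level, ]
  y <- rep(c(1, 0, 1, 0),
           c(lev$n_cases, lev$n_controls, ref$n_cases, ref$n_controls))
  exposure <- rep(c("exposed", "reference"),
                  c(lev$n_cases + lev$n_controls,
                    ref$n_cases + ref$n_controls))
  univariate_or(exposure, y, reference = "reference")
}

load_published_counts <- function() {
  utils::read.delim(system.file("extdata", "published_2x2_counts.tsv",
                                package = "miRatio"))
}
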