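test_that("pooled t-test matches stats::t.test on raw data", {
  set.seed(10)
  x <- rnorm(14, 5, 2); y <- rnorm(18, 6, 2)
  mine <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  w <- two_sample_t(x, y, var_equal = FALSE)
  refw <- t.test(x, y)
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-12)
})

test_that("summary-statistics input equals the raw-data route", {
  set.seed(11)
  x <- rnorm(10); y <- rnorm(12, 1)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t(c(mean(x), sd(x), 10), c(mean(y), sd(y), 12),
                       summary = TRUE)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
})

test_that("printed cohort MMSE summaries give p = 0.003 at three decimals", {
  res <- two_sample_t(c(26.1, 4.0, 16), c(21.7, 4.0, 19), summary = TRUE)
  expect_equal(round(res$p_value, 3), 0.003)
})

test_that("degenerate zero-variance samples follow the documented conventions", {
  expect_equal(two_sample_t(c(3, 3, 3), c(3, 3, 3))$p_value, 1)
  expect_equal(two_sample_t(c(3, 3, 3), c(4, 4, 4))$p_value, 0)
  expect_equal(two_sample_t(c(0, 1), c(0, 1))$p_value, 1)
  expect_equal(two_sample_t(c(0, 1), c(0, 1))$statistic, 0)
  expect_csf_error(two_sample_t(1, c(1, 2)), "csfpulse_stats_error")
})

test_that("Fisher exact agrees with full margin enumeration for small tables", {
  set.seed(12)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact_2x2(tab)$p_value
    expect_equal(mine, oracle_fisher_p(tab), tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))$p_value,
               oracle_fisher_p(matrix(c(1, 0, 0, 1), 2)))
})

test_that("the cohort gender tables reproduce the printed Fisher p-values", {
  # PDD-L 11M/5F vs PDD-H 13M/6F
  expect_equal(fisher_exact_2x2(matrix(c(11, 5, 13, 6), 2, byrow = TRUE))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_warning(
    res <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
    "Degenerate"
  )
  expect_equal(res$p_value, 1)
})

test_that("age residualization preserves the pooled mean and known structure", {
  set.seed(13)
  rec <- tibble::tibble(age = runif(40, 60, 85))
  # uncorrelated measure: adjustment is (numerically) the identity
  rec$flat <- rnorm(40, 10, 1)
  fit0 <- lm(flat ~ age, rec)
  rec0 <- rec
  rec0$flat <- rec$flat - coef(fit0)[2] * (rec$age - mean(rec$age)) # zero slope
  adj0 <- residualize_age(rec0, "flat")
  expect_equal(adj0$flat_age_adj, rec0$flat, tolerance = 1e-10)
  # perfectly age-determined measure collapses to the grand mean
  rec$linear <- 2 * rec$age
  adj <- residualize_age(rec, "linear")
  expect_equal(adj$linear_age_adj, rep(mean(rec$linear), 40), tolerance = 1e-10)
  # pooled mean preserved exactly for arbitrary data
  rec$noisy <- 0.5 * rec$age + rnorm(40)
  adj2 <- residualize_age(rec, "noisy")
  expect_equal(mean(adj2$noisy_age_adj), mean(rec$noisy), tolerance = 1e-12)
})

test_that("age regression recovers a known slope within two standard errors", {
  set.seed(14)
  age <- runif(60, 55, 90)
  y <- 3 + 0.5 * age + rnorm(60, 0, 1.5)
  fit <- lm(y ~ age)
  expect_lt(abs(coef(fit)[2] - 0.5), 2 * summary(fit)$coefficients[2, 2])
  expect_warning(
    residualize_age(tibble::tibble(age = rep(70, 5), m = rnorm(5)), "m"),
    "Constant age"
  )
})

test_that("bootstrap comparison handles degenerate and separated samples", {
  res <- bootstrap_pairwise(rep(2, 5), rep(2, 6), B = 1000, seed = 1)
  expect_equal(res$ci_low, 0)
  expect_equal(res$ci_high, 0)
  expect_equal(res$p_value, 1)
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20, 5)
  sep <- bootstrap_pairwise(x, y, B = 2000, seed = 2)
  expect_lt(sep$ci_high, 0)
  expect_lt(sep$p_value, 0.05)
  expect_csf_error(bootstrap_pairwise(x, y, B = 10, seed = 1),
                   "csfpulse_input_error")
  expect_csf_error(bootstrap_pairwise(x, y, B = 2000), "csfpulse_input_error")
})

test_that("bootstrap results are reproducible under a fixed seed", {
  set.seed(16)
  x <- rnorm(15); y <- rnorm(15, 1)
  a <- bootstrap_pairwise(x, y, B = 1500, seed = 99)
  b <- bootstrap_pairwise(x, y, B = 1500, seed = 99)
  expect_identical(a, b)
})

test_that("one-way ANOVA with Bonferroni isolates the deviant group", {
  g <- rep(c("A", "B", "C"), each = 10)
  set.seed(17)
  vals <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 10))
  res <- anova_bonferroni(vals, g)
  expect_lt(res$omnibus$p_value, 0.05)
  pw <- res$pairwise
  expect_gt(pw$p_value[pw$group_pair == "A vs B"], 0.05)
  expect_lt(pw$p_value[pw$group_pair == "A vs C"], 0.05)
  expect_lt(pw$p_value[pw$group_pair == "B vs C"], 0.05)
  # Bonferroni never lowers a raw p
  expect_true(all(pw$p_value >= pw$p_raw - 1e-15))
  # identical groups: omnibus F ~ 0, all adjusted p = 1
  same <- anova_bonferroni(rep(c(5, 6), 15), rep(c("A", "B", "C"), each = 10))
  expect_true(all(same$pairwise$p_value == 1))
  expect_csf_error(anova_bonferroni(rnorm(10), rep(c("A", "B"), 5)),
                   "csfpulse_input_error")
})

test_that("Pearson correlation handles exact and null relationships", {
  x <- 1:10
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  set.seed(18)
  ps <- vapply(1:40, function(i) {
    pearson_corr(rnorm(52), rnorm(52))$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)         # p roughly uniform under independence
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.05), 0.25) # rejection rate near nominal
  expect_csf_error(pearson_corr(rep(1, 5), rnorm(5)), "csfpulse_stats_error")
})

test_that("the full statistics battery runs on a synthetic cohort", {
  co <- generate_cohort(seed = 30)
  gs <- group_statistics(co, bootstrap_B = 1000, seed = 7)
  expect_true(all(gs$pairwise_t$p_value >= 0 & gs$pairwise_t$p_value <= 1))
  expect_equal(nrow(gs$gender_fisher), 3)
  expect_true(all(c("omnibus", "pairwise") %in% names(gs$anova)))
  expect_equal(nrow(gs$bootstrap_age_adj), 3)
  expect_true(all(gs$bootstrap_age_adj$ci_low <= gs$bootstrap_age_adj$ci_high))
  expect_equal(gs$age_roi_correlation$n, 52)
  # with the published group separation, HC vs PD pulsation difference shows
  hc_pd <- gs$pairwise_t[gs$pairwise_t$measure == "mean_pulse" &
                           gs$pairwise_t$group_pair == "HC vs PD", ]
  expect_lt(hc_pd$p_value, 0.05)
})
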