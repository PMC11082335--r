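#' Pooled two-sample t-test from raw data or summary statistics
#'
#' Two-sided two-sample t-test with pooled variance (the study's default;
#' Welch available via `var_equal = FALSE`). Accepts either raw sample
#' vectors or summary statistics as `c(mean, sd, n)` pairs, so printed
#' demographic tables can be tested directly.
#'
#' Zero-variance conventions (documented, needed for degenerate synthetic
#' inputs): when the pooled variance is zero the test reports `p = 1` if the
#' means are equal and `p = 0` otherwise.
#'
#' @param x,y Numeric sample vectors, or summary statistics `c(mean, sd, n)`
#'   when `summary = TRUE`.
#' @param summary Interpret `x` and `y` as `c(mean, sd, n)` summaries.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @param measure,group_pair Labels carried into the result row.
#' @return One-row `group_comparison` tibble: `measure`, `group_pair`,
#'   `method`, `statistic`, `p_value`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @examples
#' # printed MMSE summaries: (26.1, 4.0, 16) vs (21.7, 4.0, 19)
#' two_sample_t(c(26.1, 4.0, 16), c(21.7, 4.0, 19), summary = TRUE)$p_value
#' @export
two_sample_t <- function(x, y, summary = FALSE, var_equal = TRUE,
                         measure = NA_character_, group_pair = NA_character_) {
  if (summary) {
    if (length(x) != 3 || length(y) != 3)
      stop_csf("Summary input must be c(mean, sd, n) per group.",
               "csfpulse_input_error")
    m1 <- x[1]; s1 <- x[2]; n1 <- x[3]
    m2 <- y[1]; s2 <- y[2]; n2 <- y[3]
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    m1 <- mean(x); s1 <- sd(x); n1 <- length(x)
    m2 <- mean(y); s2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2)
    stop_csf("Each group needs n >= 2.", "csfpulse_stats_error")
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  if (se == 0 || !is.finite(df)) {
    tstat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    tstat <- (m1 - m2) / se
    p <- 2 * pt(-abs(tstat), df)
  }
  group_comparison_row(
    measure = measure, group_pair = group_pair,
    method = if (var_equal) "t_test" else "t_test_welch",
    statistic = tstat, p_value = p, n1 = n1, n2 = n2
  )
}

group_comparison_row <- function(measure, group_pair, method, statistic,
                                 p_value, ci_low = NA_real_, ci_high = NA_real_,
                                 n1 = NA_integer_, n2 = NA_integer_) {
  out <- tibble(
    measure = measure, group_pair = group_pair, method = method,
    statistic = statistic, p_value = p_value,
    ci_low = ci_low, ci_high = ci_high,
    n1 = as.integer(n1), n2 = as.integer(n2)
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by summing the probabilities of all tables (under
#' fixed margins) no more probable than the observed one, as used for the
#' cohort's gender distributions. Thin wrapper over [stats::fisher.test()]
#' with a degenerate-margin convention: a zero row or column margin yields
#' `p = 1` with a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param measure,group_pair Labels carried into the result row.
#' @return One-row `group_comparison` tibble; `statistic` is the sample odds
#'   ratio (conditional MLE from `fisher.test` when defined).
#' @examples
#' fisher_exact_2x2(matrix(c(11, 5, 13, 6), 2, byrow = TRUE))$p_value # 1
#' @export
fisher_exact_2x2 <- function(tab, measure = NA_character_,
                             group_pair = NA_character_) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop_csf("`tab` must be a 2x2 matrix of non-negative integer counts.",
             "csfpulse_input_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::warn("Degenerate 2x2 table (zero margin): p = 1 by convention.")
    return(group_comparison_row(measure, group_pair, "fisher_exact",
                                statistic = NA_real_, p_value = 1,
                                n1 = sum(tab[1, ]), n2 = sum(tab[2, ])))
  }
  ft <- stats::fisher.test(tab)
  group_comparison_row(measure, group_pair, "fisher_exact",
                       statistic = unname(ft$estimate), p_value = ft$p.value,
                       n1 = sum(tab[1, ]), n2 = sum(tab[2, ]))
}

#' Residualize a measure on age
#'
#' Removes the age covariance from a derived measure by ordinary least
#' squares across all subjects pooled (a single covariate correction, not
#' per-group fits): the adjusted value is the regression residual plus the
#' grand mean, so the pooled mean of the measure is preserved exactly and
#' group labels are untouched.
#'
#' @param records Data frame with an `age` column and the `measure` column.
#' @param measure Name of the measure column to adjust.
#' @return `records` with an added `<measure>_age_adj` column.
#' @export
residualize_age <- function(records, measure) {
  if (!all(c("age", measure) %in% names(records)))
    stop_csf(sprintf("`records` must have columns `age` and `%s`.", measure),
             "csfpulse_input_error")
  y <- records[[measure]]
  age <- records$age
  ok <- is.finite(y) & is.finite(age)
  if (sum(ok) < 3)
    stop_csf("At least 3 subjects with age and measure are required.",
             "csfpulse_stats_error")
  adj_col <- paste0(measure, "_age_adj")
  if (sd(age[ok]) == 0) {
    rlang::warn("Constant age: adjustment skipped (identity mapping).")
    records[[adj_col]] <- y
    return(records)
  }
  fit <- lm(y ~ age, data = data.frame(y = y[ok], age = age[ok]))
  adj <- rep(NA_real_, length(y))
  adj[ok] <- stats::residuals(fit) + mean(y[ok])
  records[[adj_col]] <- adj
  records
}

#' Bootstrap pairwise comparison of group means
#'
#' Percentile bootstrap of the mean difference `mean(x) - mean(y)`:
#' resamples within each group with replacement, reports the 95% percentile
#' confidence interval and a two-sided p-value
#' `2 * min(P(diff <= 0), P(diff >= 0))` capped at 1.
#'
#' @param x,y Numeric sample vectors.
#' @param B Number of bootstrap replicates (`>= 1000`).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param conf Confidence level of the percentile interval.
#' @param measure,group_pair Labels carried into the result row.
#' @return One-row `group_comparison` tibble; `statistic` is the observed
#'   mean difference.
#' @export
bootstrap_pairwise <- function(x, y, B = 10000, seed,
                               conf = 0.95,
                               measure = NA_character_,
                               group_pair = NA_character_) {
  if (B < 1000)
    stop_csf("`B` must be >= 1000 bootstrap replicates.", "csfpulse_input_error")
  if (missing(seed) || !is.numeric(seed))
    stop_csf("A numeric `seed` is required for reproducibility.",
             "csfpulse_input_error")
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop_csf("Samples must be non-empty.", "csfpulse_input_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bx <- matrix(sample(x, length(x) * B, replace = TRUE), nrow = B)
  by <- matrix(sample(y, length(y) * B, replace = TRUE), nrow = B)
  diffs <- rowMeans(bx) - rowMeans(by)
  ci <- unname(quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  group_comparison_row(measure, group_pair, "bootstrap",
                       statistic = mean(x) - mean(y), p_value = p,
                       ci_low = ci[1], ci_high = ci[2],
                       n1 = length(x), n2 = length(y))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Omnibus one-way ANOVA (pooled variance) across three or more groups,
#' followed by pairwise pooled t-tests whose p-values are multiplied by the
#' number of pairs (Bonferroni) and capped at 1.
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation (>= 3 distinct levels, each with
#'   n >= 2).
#' @param measure Label carried into the result rows.
#' @return List with `omnibus` (one-row tibble: F statistic, df, p) and
#'   `pairwise` (`group_comparison` tibble with raw and Bonferroni-adjusted
#'   p-values).
#' @export
anova_bonferroni <- function(values, group, measure = NA_character_) {
  group <- as.character(group)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  levels <- sort(unique(group))
  if (length(levels) < 3)
    stop_csf("At least 3 groups are required.", "csfpulse_input_error")
  counts <- table(group)
  if (any(counts < 2))
    stop_csf("Every group needs n >= 2.", "csfpulse_stats_error")
  ow <- stats::oneway.test(values ~ factor(group), var.equal = TRUE)
  omnibus <- tibble(
    measure = measure, method = "anova_oneway",
    statistic = unname(ow$statistic),
    df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
    p_value = ow$p.value
  )
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  m <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    row <- two_sample_t(values[group == pr[1]], values[group == pr[2]],
                        measure = measure,
                        group_pair = paste(pr, collapse = " vs "))
    row$method <- "anova_bonferroni"
    row$p_raw <- row$p_value
    row$p_value <- min(1, row$p_value * m)
    row
  })
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-zero variance.
#' @param measure Label carried into the result row.
#' @return One-row tibble: `measure`, `method`, `r`, `statistic` (t), `n`,
#'   `p_value`.
#' @export
pearson_corr <- function(x, y, measure = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    stop_csf("Need equal-length samples with n >= 3.", "csfpulse_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_csf("Correlation undefined: zero variance in a sample.",
             "csfpulse_stats_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(measure = measure, method = "pearson",
         r = unname(ct$estimate), statistic = unname(ct$statistic),
         n = length(x), p_value = ct$p.value)
}

#' Group-level statistics of a cohort results table
#'
#' Reproduces the study's statistical battery on a per-subject results table:
#' pairwise pooled t-tests on each derived measure (HC vs pooled PD, and all
#' group pairs), Fisher exact tests on gender, one-way ANOVA with Bonferroni
#' on CSF pulsation (before and after age adjustment), bootstrap pairwise
#' comparisons of the age-adjusted pulsation, and the Pearson correlation
#' between age and ROI size.
#'
#' @param records Per-subject tibble with columns `group` (HC / PDD-L /
#'   PDD-H), `gender`, `age`, and derived measures `mean_pulse`,
#'   `abs_z_mean`, `positive_ratio`, `n_voxels`.
#' @param measures Derived measures to compare pairwise.
#' @param bootstrap_B,seed Bootstrap replicates and seed (see
#'   [bootstrap_pairwise()]).
#' @return List of tibbles: `pairwise_t`, `gender_fisher`, `anova`,
#'   `anova_age_adj`, `bootstrap_age_adj`, `age_roi_correlation`.
#' @export
group_statistics <- function(records,
                             measures = c("mean_pulse", "abs_z_mean",
                                          "positive_ratio", "n_voxels"),
                             bootstrap_B = 10000, seed = 1) {
  needed <- c("group", "gender", "age", measures)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop_csf(sprintf("`records` is missing column(s): %s.",
                     paste(missing_cols, collapse = ", ")),
             "csfpulse_input_error")
  grp <- as.character(records$group)
  levels <- sort(unique(grp))
  pairs <- c(list(c("HC", "PD")), utils::combn(levels, 2, simplify = FALSE))

  value_of <- function(measure, g) {
    if (g == "PD") records[[measure]][grp != "HC"]
    else records[[measure]][grp == g]
  }
  pairwise_t <- purrr::map_dfr(measures, function(ms) {
    purrr::map_dfr(pairs, function(pr) {
      x <- value_of(ms, pr[1]); y <- value_of(ms, pr[2])
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      two_sample_t(x, y, measure = ms, group_pair = paste(pr, collapse = " vs "))
    })
  })

  gender_fisher <- purrr::map_dfr(utils::combn(levels, 2, simplify = FALSE),
    function(pr) {
      tab <- rbind(table(factor(records$gender[grp == pr[1]], levels = c("M", "F"))),
                   table(factor(records$gender[grp == pr[2]], levels = c("M", "F"))))
      fisher_exact_2x2(tab, measure = "gender",
                       group_pair = paste(pr, collapse = " vs "))
    })

  an <- anova_bonferroni(records$mean_pulse, grp, measure = "mean_pulse")
  adj <- residualize_age(records, "mean_pulse")
  an_adj <- anova_bonferroni(adj$mean_pulse_age_adj, grp,
                             measure = "mean_pulse_age_adj")
  boot <- purrr::map_dfr(utils::combn(levels, 2, simplify = FALSE),
    function(pr) {
      bootstrap_pairwise(adj$mean_pulse_age_adj[grp == pr[1]],
                         adj$mean_pulse_age_adj[grp == pr[2]],
                         B = bootstrap_B, seed = seed,
                         measure = "mean_pulse_age_adj",
                         group_pair = paste(pr, collapse = " vs "))
    })
  age_roi <- pearson_corr(records$age, records$n_voxels,
                          measure = "age_vs_n_voxels")
  list(pairwise_t = pairwise_t, gender_fisher = gender_fisher,
       anova = an, anova_age_adj = an_adj,
       bootstrap_age_adj = boot, age_roi_correlation = age_roi)
}

#' Type-I error calibration of the group test on null cohorts
#'
#' Repeatedly generates signal-level cohorts in which all three groups share
#' the same pulsation distribution, runs the omnibus one-way ANOVA on the
#' per-subject mean pulsation, and reports the rejection rate at the nominal
#' level. For a calibrated test the rate should be close to `alpha_level`.
#'
#' @param n_reps Number of simulated null cohorts.
#' @param seed RNG seed.
#' @param alpha_level Nominal significance level.
#' @param n_per_group Subjects per group (defaults to the study's 17/16/19).
#' @return List: `rate`, `n_reps`, `alpha_level`, `rejections`.
#' @export
type1_error_rate <- function(n_reps = 500, seed = 1, alpha_level = 0.05,
                             n_per_group = c(HC = 17, `PDD-L` = 16, `PDD-H` = 19)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  grp <- factor(rep(names(n_per_group), n_per_group))
  n_tot <- sum(n_per_group)
  rej <- vapply(seq_len(n_reps), function(i) {
    vals <- rnorm(n_tot, mean = 10, sd = 3)
    stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value < alpha_level
  }, logical(1))
  list(rate = mean(rej), n_reps = n_reps, alpha_level = alpha_level,
       rejections = sum(rej))
}

#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group_pair, y = .data$p_value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "p-value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
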