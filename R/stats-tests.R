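#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled`, pooling variances with n-1 weights.
#'
#' @param x,y Numeric vectors (each at least 2 values).
#' @return d, or NA when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("Need at least 2 values per group.")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

shapiro_ok <- function(x) {
  # Shapiro-Wilk is undefined for constant samples and capped at n=5000
  if (length(unique(x)) < 3) return(NA)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  shapiro.test(x)$p.value > 0.05
}

#' Normality-gated two-group comparison
#'
#' Runs Shapiro–Wilk on both groups; if both look normal (p > 0.05) the
#' groups are compared with a pooled-variance two-sample t-test,
#' otherwise with a Mann–Whitney U test. The p-value is Bonferroni
#' multiplied by `bonferroni_k` (clamped at 1), Cohen's d is always
#' attached, and for non-significant results the achieved power of a
#' d = 0.5 two-sample t-test at these group sizes is reported.
#'
#' @param x,y Numeric vectors (at least 3 per group).
#' @param alpha Significance level.
#' @param bonferroni_k Bonferroni correction factor (number of tests in
#'   the family).
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return A one-row tibble (`test`, `n1`, `n2`, `statistic`, `p_raw`,
#'   `p_adjusted`, `adjust_method`, `cohens_d`, `achieved_power`).
#' @export
compare_groups <- function(x, y, alpha = 0.05, bonferroni_k = 1,
                           welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) abort("Need at least 3 values per group.")
  nx <- shapiro_ok(x); ny <- shapiro_ok(y)
  if (is.na(nx) || is.na(ny)) {
    inform("Constant group values: normality undefined, using Mann-Whitney U.")
  }
  normal <- isTRUE(nx) && isTRUE(ny)
  if (normal) {
    ht <- t.test(x, y, var.equal = !welch)
    test <- if (welch) "welch_t" else "t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    test <- "mann_whitney_u"
  }
  p_adj <- min(1, ht$p.value * bonferroni_k)
  tibble(
    test = test, n1 = length(x), n2 = length(y),
    statistic = unname(ht$statistic), p_raw = ht$p.value,
    p_adjusted = p_adj,
    adjust_method = if (bonferroni_k > 1) sprintf("bonferroni_x%d", bonferroni_k) else "none",
    cohens_d = cohens_d(x, y),
    achieved_power = if (p_adj >= alpha) {
      achieved_power(length(x), length(y), d = 0.5, alpha = alpha)
    } else {
      NA_real_
    }
  )
}

#' Wilcoxon signed-rank test of paired differences against zero
#'
#' @param diffs Numeric vector of differences (at least 6 non-zero).
#' @param alpha Significance level.
#' @param bonferroni_k Bonferroni factor.
#' @return A one-row tibble in the [compare_groups()] layout (with
#'   `cohens_d` = mean/SD of the differences, the one-sample d).
#' @export
signed_rank_vs_zero <- function(diffs, alpha = 0.05, bonferroni_k = 1) {
  diffs <- diffs[!is.na(diffs)]
  nz <- diffs[diffs != 0]
  if (length(diffs) > 0 && length(nz) == 0) {
    inform("All differences are zero; returning p = 1 by convention.")
    return(tibble(test = "wilcoxon_signed_rank", n1 = length(diffs),
                  n2 = NA_integer_, statistic = NA_real_, p_raw = 1,
                  p_adjusted = 1, adjust_method = "none", cohens_d = 0,
                  achieved_power = NA_real_))
  }
  if (length(nz) < 6) abort("Need at least 6 non-zero differences.")
  ht <- suppressWarnings(wilcox.test(nz, mu = 0, exact = FALSE))
  p_adj <- min(1, ht$p.value * bonferroni_k)
  tibble(
    test = "wilcoxon_signed_rank", n1 = length(diffs), n2 = NA_integer_,
    statistic = unname(ht$statistic), p_raw = ht$p.value,
    p_adjusted = p_adj,
    adjust_method = if (bonferroni_k > 1) sprintf("bonferroni_x%d", bonferroni_k) else "none",
    cohens_d = mean(diffs) / sd(diffs),
    achieved_power = NA_real_
  )
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Pooled-variance two-sample TOST: rejects non-equivalence when the
#' group difference is significantly above `-margin` *and* significantly
#' below `+margin`. Equivalence margins follow the trial's pre-specified
#' values (5 bpm for heart rate, 50 ms for QT, 2 mmHg for blood
#' pressure).
#'
#' @param x,y Numeric vectors (at least 3 per group).
#' @param margin Positive equivalence margin, in the metric's units.
#' @param alpha One-sided level for each test.
#' @return A one-row tibble: `margin`, `mean_diff`, `t_lower`,
#'   `p_lower`, `t_upper`, `p_upper`, `equivalent`.
#' @export
tost_equivalence <- function(x, y, margin, alpha = 0.05) {
  if (margin <= 0) abort("`margin` must be positive.")
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) abort("Need at least 3 values per group.")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  diff <- mean(x) - mean(y)
  t_lower <- (diff + margin) / se   # H0: diff <= -margin
  t_upper <- (diff - margin) / se   # H0: diff >= +margin
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df, lower.tail = TRUE)
  tibble(margin = margin, mean_diff = diff, n1 = n1, n2 = n2,
         t_lower = t_lower, p_lower = p_lower,
         t_upper = t_upper, p_upper = p_upper,
         equivalent = max(p_lower, p_upper) < alpha)
}

#' Pearson correlation with its t-test
#'
#' @param x,y Numeric vectors (at least 4 complete pairs).
#' @return A one-row tibble: `r`, `statistic`, `p_value`, `n` (NA values
#'   pairwise-dropped; zero-variance input yields NA r).
#' @export
pearson_with_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort("Need at least 4 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, statistic = NA_real_, p_value = NA_real_,
                  n = length(x)))
  }
  ct <- cor.test(x, y)
  tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = length(x))
}
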