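test_that("Cohen's d matches its definition and degenerates safely", {
  set.seed(1)
  x <- rnorm(100)
  expect_equal(cohens_d(x, x), 0)

  x2 <- rnorm(5000, 1, 1); y2 <- rnorm(5000, 0, 1)
  expect_lt(abs(cohens_d(x2, y2) - 1), 0.1)

  # brute-force identity on random draws
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(25)
    sp <- sqrt(((29) * var(a) + (24) * var(b)) / 53)
    expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  }
  expect_true(is.na(cohens_d(rep(1, 5), rep(1, 5))))
  expect_error(cohens_d(1, 1:5), "at least 2")
})

test_that("group comparison gates on normality and clamps Bonferroni", {
  set.seed(2)
  x <- rnorm(500)
  r <- compare_groups(x, x)
  expect_equal(r$cohens_d, 0)
  expect_gt(r$p_raw, 0.5)
  expect_equal(r$test, "t")

  shift <- compare_groups(rnorm(500, 1), rnorm(500, 0), bonferroni_k = 1)
  expect_lt(abs(shift$cohens_d - 1), 0.1)

  skewed <- compare_groups(rexp(200), rexp(200))
  expect_equal(skewed$test, "mann_whitney_u")

  clamped <- compare_groups(rnorm(40), rnorm(40), bonferroni_k = 6)
  expect_lte(clamped$p_adjusted, 1)
  if (clamped$p_raw > 1 / 6) expect_equal(clamped$p_adjusted, 1)

  expect_message(const <- compare_groups(rep(1, 10), rnorm(10)), "Constant")
  expect_equal(const$test, "mann_whitney_u")

  # power attached exactly when non-significant
  expect_false(is.na(r$achieved_power))
  sig <- compare_groups(rnorm(200, 2), rnorm(200, 0))
  expect_true(is.na(sig$achieved_power))
})

test_that("signed-rank test handles nulls, extremes and preconditions", {
  set.seed(3)
  r <- signed_rank_vs_zero(rnorm(50))
  expect_gt(r$p_raw, 0.05)

  ones <- signed_rank_vs_zero(rep(1, 20))
  expect_lt(ones$p_raw, 0.001)

  expect_error(signed_rank_vs_zero(c(1, -1, 2, -2, 1)), "at least 6")
  expect_message(z <- signed_rank_vs_zero(rep(0, 10)), "zero")
  expect_equal(z$p_raw, 1)
})

test_that("TOST declares equivalence only inside the margin", {
  set.seed(4)
  x <- rnorm(200); y <- rnorm(200)
  eq <- tost_equivalence(x, y, margin = 5)
  expect_true(eq$equivalent)

  y2 <- rnorm(200, mean = 10)   # true difference = 2x margin
  neq <- tost_equivalence(x, y2, margin = 5)
  expect_false(neq$equivalent)

  wide <- tost_equivalence(x, y, margin = 1e6)
  expect_lt(wide$p_lower, 1e-10)
  expect_lt(wide$p_upper, 1e-10)

  expect_error(tost_equivalence(x, y, margin = -1), "positive")
})

test_that("difference and equivalence cannot both hold beyond the margin", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(100)
    y <- rnorm(100, mean = 4)  # |true diff| > margin = 2
    diff_sig <- t.test(x, y, var.equal = TRUE)$p.value < 0.05
    eq <- tost_equivalence(x, y, margin = 2)$equivalent
    expect_false(diff_sig && eq)
  }
})

test_that("power analytics reproduce the trial's printed values", {
  expect_equal(round(achieved_power(94, 95, d = 0.5, alpha = 0.05), 2),
               0.93)
  expect_equal(required_n_per_group(0.80, 0.5, 0.05), 64)

  expect_equal(achieved_power(50, 50, d = 0), 0.05, tolerance = 1e-10)
  pw <- vapply(c(10, 20, 40, 80, 160),
               function(n) achieved_power(n, 95, d = 0.5), numeric(1))
  expect_true(all(diff(pw) > 0))

  n64 <- required_n_per_group(0.80, 0.5, 0.05)
  expect_gte(achieved_power(n64, n64, 0.5), 0.80)
  expect_lt(achieved_power(n64 - 1, n64 - 1, 0.5), 0.80)
  expect_lt(required_n_per_group(0.80, d = 1.0), n64)
})

test_that("Pearson helper matches construction and controls type I error", {
  x <- 1:50
  expect_equal(pearson_with_test(x, x)$r, 1)

  set.seed(6)
  xr <- rnorm(100)
  r <- pearson_with_test(xr, -xr + rnorm(100, 0, 0.1))
  expect_lt(r$r, -0.9)
  expect_lt(r$p_value, 1e-10)

  rej <- replicate(1000, pearson_with_test(rnorm(20), rnorm(20))$p_value < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 0.02)

  expect_true(is.na(pearson_with_test(rep(1, 10), rnorm(10))$r))
})

test_that("the outcome model recovers injected interaction slopes", {
  spec <- cohort_spec(n_tavns = 12, n_sham = 12, days_mean = 10, days_sd = 2,
                      acute_hr_jump = 1, mrs_slope = -1.85, seed = 31)
  out <- simulate_session_outcomes(spec)
  fit <- fit_outcome_model(out)
  co <- tidy(fit)
  ia <- co[co$term == "treated_x_mrs_change", ]
  expect_lt(ia$conf_low, -1.85)
  expect_gt(ia$conf_high, -1.85)

  # permuting subjects' outcomes attenuates the interaction
  set.seed(7)
  perm <- out
  key <- unique(out[, c("subject_id", "mrs_change")])
  key$mrs_change <- sample(key$mrs_change)
  perm$mrs_change <- key$mrs_change[match(perm$subject_id, key$subject_id)]
  fits <- fit_outcome_model(perm)
  ia_p <- tidy(fits)[tidy(fits)$term == "treated_x_mrs_change", ]
  expect_lt(abs(ia_p$estimate), abs(ia$estimate) + 1)

  # null slope: CI covers zero
  spec0 <- cohort_spec(n_tavns = 12, n_sham = 12, days_mean = 10,
                       days_sd = 2, acute_hr_jump = 0, mrs_slope = 0,
                       seed = 32)
  fit0 <- fit_outcome_model(simulate_session_outcomes(spec0))
  ia0 <- tidy(fit0)[tidy(fit0)$term == "treated_x_mrs_change", ]
  expect_lt(ia0$conf_low, 0)
  expect_gt(ia0$conf_high, 0)

  expect_error(fit_outcome_model(out[, -2]), "lacks")
})

test_that("age-adjusted ANCOVA recovers null and injected age slopes", {
  set.seed(8)
  n <- 200
  d <- tibble::tibble(
    group = rep(c("taVNS", "Sham"), each = n / 2),
    age_decade = sample(seq(30, 80, 10), n, replace = TRUE),
    change = rnorm(n) + 0.5 * (rep(c(1, 0), each = n / 2))
  )
  a0 <- ancova_age(d, "change")
  age_row <- a0[a0$term == "age_decade", ]
  expect_lt(abs(age_row$estimate), 0.02)

  d2 <- d
  d2$change <- d2$change - 0.05 * (d2$age_decade - 50)
  a2 <- ancova_age(d2, "change")
  age2 <- a2[a2$term == "age_decade", ]
  expect_lt(abs(age2$estimate - (-0.05)), 0.02)
  expect_lt(age2$p_value, 0.001)

  # age orthogonal to group: treatment estimate barely moves
  trt_with <- a0[startsWith(a0$term, "treated"), ]$estimate
  plain <- lm(change ~ group == "taVNS", data = d)
  expect_lt(abs(trt_with - coef(plain)[2]), 0.1)

  d3 <- d
  d3$age_decade <- 50
  expect_message(a3 <- ancova_age(d3, "change"), "constant")
  expect_false(any(a3$term == "age_decade"))
})
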