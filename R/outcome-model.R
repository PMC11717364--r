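#' Random-intercept model linking acute heart-rate change to outcome
#'
#' Fits the treatment-by-outcome interaction model for the per-session
#' acute heart-rate change:
#' `hr_change ~ group + mrs_change + group:mrs_change + (1 | subject)`,
#' i.e. fixed intercept, a treatment offset, an mRS-change slope, an
#' additional slope for the treated arm, and a random intercept per
#' subject (REML). A negative treated-arm slope means larger acute
#' heart-rate increases in subjects whose disability score improved.
#'
#' @param data Session-level data frame with columns `subject_id`,
#'   `group` (`taVNS`/`Sham` or any two levels; the non-reference level
#'   is taken as treated), `mrs_change` and the response column.
#' @param response Name of the response column (default `hr_change`).
#' @param conf_method Confidence-interval method passed to
#'   [lme4::confint.merMod()] (`"Wald"` is fast and adequate for the
#'   recovery studies; `"profile"` is available).
#' @return An object of class `hrv_outcome_fit` wrapping the
#'   `lmerMod` fit, with tidy coefficient and variance summaries.
#' @export
fit_outcome_model <- function(data, response = "hr_change",
                              conf_method = "Wald") {
  need <- c("subject_id", "group", "mrs_change", response)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` lacks columns: ", paste(miss, collapse = ", ")))
  }
  per_subj <- table(data$subject_id)
  if (mean(per_subj >= 2) < 0.5) {
    warn("Fewer than half the subjects have 2+ sessions; random intercepts are weakly identified.")
  }
  df <- data
  df$group <- factor(df$group)
  if ("taVNS" %in% levels(df$group)) df$group <- stats::relevel(df$group, "Sham")
  fml <- stats::as.formula(
    paste(response, "~ group * mrs_change + (1 | subject_id)"))
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  if (lme4::isSingular(fit)) {
    warn("Random-effects fit is singular; subject variance estimated at the boundary.")
  }
  ci <- suppressMessages(confint(fit, method = conf_method,
                                 parm = "beta_"))
  sm <- summary(fit)$coefficients
  treated_lv <- setdiff(levels(df$group), levels(df$group)[1])[1]
  nice <- c("(Intercept)" = "intercept",
            setNames("treated", paste0("group", treated_lv)),
            "mrs_change" = "mrs_change",
            setNames("treated_x_mrs_change",
                     paste0("group", treated_lv, ":mrs_change")))
  # a degenerate design (e.g. mRS constant within an arm) drops terms;
  # keep the full four-term layout with NA for anything unidentified
  coefs <- tibble(term = unname(nice),
                  estimate = NA_real_, std_error = NA_real_,
                  p_value = NA_real_, conf_low = NA_real_,
                  conf_high = NA_real_)
  for (rn in rownames(sm)) {
    i <- match(unname(nice[rn]), coefs$term)
    if (is.na(i)) next
    coefs$estimate[i] <- sm[rn, "Estimate"]
    coefs$std_error[i] <- sm[rn, "Std. Error"]
    coefs$p_value[i] <- sm[rn, "Pr(>|t|)"]
    if (rn %in% rownames(ci)) {
      coefs$conf_low[i] <- ci[rn, 1]
      coefs$conf_high[i] <- ci[rn, 2]
    }
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(fit = fit, coefficients = coefs,
         subject_sd = vc$sdcor[vc$grp == "subject_id"][1],
         residual_sd = vc$sdcor[vc$grp == "Residual"][1],
         n_sessions = nrow(df), n_subjects = length(unique(df$subject_id)),
         singular = lme4::isSingular(fit)),
    class = "hrv_outcome_fit"
  )
}

#' @export
print.hrv_outcome_fit <- function(x, ...) {
  cat(sprintf("<hrv_outcome_fit: %d sessions, %d subjects; subject SD %.2f, residual SD %.2f>\n",
              x$n_sessions, x$n_subjects, x$subject_sd, x$residual_sd))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @describeIn fit_outcome_model Coefficients in tidy form.
#' @param x An `hrv_outcome_fit`.
#' @param ... Unused.
#' @export
tidy.hrv_outcome_fit <- function(x, ...) x$coefficients

#' @describeIn fit_outcome_model One-row fit summary.
#' @export
glance.hrv_outcome_fit <- function(x, ...) {
  tibble(n_sessions = x$n_sessions, n_subjects = x$n_subjects,
         subject_sd = x$subject_sd, residual_sd = x$residual_sd,
         singular = x$singular,
         interaction = x$coefficients$estimate[4],
         interaction_p = x$coefficients$p_value[4])
}

#' Age-adjusted group comparison (ANCOVA)
#'
#' Linear model `change ~ group + age`, giving the treatment effect
#' adjusted for age and the age slope itself. With constant age the age
#' term is dropped (with a message).
#'
#' @param data Data frame with the response column, `group`, and
#'   `age_decade`.
#' @param response Name of the response column.
#' @return A tibble with one row per term (`treated`, `age_decade`):
#'   estimate, standard error, p-value, 95% CI.
#' @export
ancova_age <- function(data, response) {
  need <- c(response, "group", "age_decade")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (anyNA(data$age_decade)) abort("Age must be available for all rows.")
  df <- data
  df$group <- factor(df$group)
  if ("taVNS" %in% levels(df$group)) df$group <- stats::relevel(df$group, "Sham")
  with_age <- length(unique(df$age_decade)) > 1
  if (!with_age) inform("Age is constant; dropping the age covariate.")
  fml <- stats::as.formula(paste(
    response, if (with_age) "~ group + age_decade" else "~ group"))
  fit <- lm(fml, data = df)
  sm <- summary(fit)$coefficients
  ci <- confint(fit)
  terms <- rownames(sm)[-1]
  tibble(
    term = sub("^group", "treated:", sub("^age_decade$", "age_decade", terms)),
    estimate = unname(sm[-1, 1]), std_error = unname(sm[-1, 2]),
    p_value = unname(sm[-1, 4]),
    conf_low = unname(ci[-1, 1]), conf_high = unname(ci[-1, 2])
  )
}
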