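#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the analysis into one serializable list: the
#' cohort source (a [cohort_spec()] to simulate, or a directory of
#' cohort CSVs), window geometry, spectral band edges, equivalence
#' margins, significance level and the Bonferroni family sizes.
#'
#' @param cohort A [cohort_spec()], or NULL when `input_dir` is given.
#' @param input_dir Directory holding `subjects.csv`, `sessions.csv`,
#'   `beats.csv` (and optionally `vitals.csv`), as written by
#'   [write_cohort()].
#' @param out_dir Output directory for artifacts (NULL: no files
#'   written).
#' @param seed Integer seed recorded in the manifest (the cohort spec's
#'   own seed governs simulation).
#' @param window,step Sliding-window length and step (s).
#' @param min_ref Minimum reference windows for daily normalization.
#' @param alpha Significance level.
#' @param bonferroni_cardiac,bonferroni_vascular Bonferroni family sizes
#'   for the cardiac battery (six metrics: HR, QTc, RMSSD, SDNN and the
#'   two factors) and the vascular battery.
#' @param margins Equivalence margins: `hr` (bpm), `qt` (ms), `bp`
#'   (mmHg).
#' @param spectral Compute frequency-domain metrics per window.
#' @param n_factors Number of factors to extract.
#' @param overwrite Overwrite existing artifacts in `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL,
                            out_dir = NULL, seed = 1L, window = 360,
                            step = 180, min_ref = 20, alpha = 0.05,
                            bonferroni_cardiac = 6,
                            bonferroni_vascular = 4,
                            margins = c(hr = 5, qt = 50, bp = 2),
                            spectral = TRUE, n_factors = 2,
                            overwrite = FALSE) {
  if (is.null(cohort) && is.null(input_dir)) {
    abort("Provide either a `cohort` spec to simulate or an `input_dir`.")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(sprintf("`input_dir` does not exist: %s", input_dir))
  }
  if (!all(c("hr", "qt", "bp") %in% names(margins))) {
    abort("`margins` must name `hr`, `qt` and `bp`.")
  }
  structure(
    list(cohort = cohort, input_dir = input_dir, out_dir = out_dir,
         seed = as.integer(seed), window = window, step = step,
         min_ref = min_ref, alpha = alpha,
         bonferroni_cardiac = bonferroni_cardiac,
         bonferroni_vascular = bonferroni_vascular, margins = margins,
         spectral = spectral, n_factors = n_factors,
         overwrite = overwrite),
    class = "pipeline_config"
  )
}

#' Read a cohort back from its CSV artifacts
#' @param dir Directory written by [write_cohort()].
#' @return An `hrv_cohort` list (without a spec).
#' @export
read_cohort <- function(dir) {
  need <- c("subjects.csv", "sessions.csv", "beats.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss) > 0) {
    abort(paste0("Cohort directory lacks: ", paste(miss, collapse = ", ")))
  }
  vit_path <- file.path(dir, "vitals.csv")
  structure(
    list(spec = NULL,
         subjects = readr::read_csv(file.path(dir, "subjects.csv"),
                                    show_col_types = FALSE),
         sessions = readr::read_csv(file.path(dir, "sessions.csv"),
                                    show_col_types = FALSE),
         beats = readr::read_csv(file.path(dir, "beats.csv"),
                                 show_col_types = FALSE),
         vitals = if (file.exists(vit_path)) {
           readr::read_csv(vit_path, show_col_types = FALSE)
         }),
    class = "hrv_cohort"
  )
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes treatment-locked sliding
#' windows with daily normalization and session contrasts, daily
#' summaries with Day 1 anchoring, the two-factor autonomic model, and
#' the trial statistics battery. Artifacts are written as plain-text
#' CSV/JSON when the config names an output directory.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `hrv_pipeline`: `cohort`, `windows`,
#'   `contrasts`, `daily`, `factors`, `stats`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    simulate_cohort(config$cohort)
  }

  windows <- cohort$beats |>
    dplyr::group_split(.data$subject_id, .data$day) |>
    map(function(b) {
      eps <- filter(cohort$sessions,
                    .data$subject_id == b$subject_id[1],
                    .data$day == b$day[1])
      w <- windowed_metrics(b, eps, window = config$window,
                           step = config$step,
                           spectral = config$spectral)
      w$subject_id <- b$subject_id[1]
      w$day <- b$day[1]
      w
    }) |>
    list_rbind() |>
    normalize_daily(min_ref = config$min_ref)

  contrasts <- session_contrasts(windows)
  daily <- daily_summaries(cohort$beats, cohort$vitals,
                           spectral = config$spectral)

  factors <- NULL
  if (config$spectral) {
    fx_in <- factor_input(windows)
    factors <- fit_hrv_factors(fx_in, n_factors = config$n_factors)
    if (!anyNA(factors$labels)) {
      daily <- bind_rows(daily, factor_daily_scores(factors, windows))
    }
  }

  stats <- trial_stats(daily, contrasts, cohort$subjects, config)

  result <- structure(
    list(cohort = cohort, windows = windows, contrasts = contrasts,
         daily = daily, factors = factors, stats = stats,
         config = config),
    class = "hrv_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

# daily factor scores (mean window score per subject-day), shaped like
# the other daily metrics so they join the group-comparison battery
factor_daily_scores <- function(factors, windows) {
  zcols <- paste0("z_", rownames(factors$loadings))
  x <- windows[, zcols]
  names(x) <- rownames(factors$loadings)
  sc <- score_factors(factors, x)
  sc$subject_id <- windows$subject_id
  sc$day <- windows$day
  sc |>
    tidyr::pivot_longer(dplyr::all_of(unname(factors$labels)),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$subject_id, .data$day, .data$metric) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    group_by(.data$subject_id, .data$metric) |>
    mutate(change_from_day1 = .data$value -
             .data$value[match(1, .data$day)]) |>
    ungroup() |>
    mutate(day_bin = day_bin_of(.data$day))
}

cardiac_battery <- c("hr", "qtc_mean", "rmssd", "sdnn", "overall_hrv",
                     "parasympathetic")
vascular_battery <- c("bp_mean_mmHg", "ppi", "resp_rate_bpm", "icp_mmHg")

#' Trial statistics battery
#'
#' Group comparisons of daily changes (normality-gated, Bonferroni
#' within the cardiac and vascular families, overall and by 3-day bin),
#' TOST equivalence for heart rate / QTc / blood pressure changes,
#' signed-rank tests of the acute post-minus-during heart-rate change
#' per arm, the PPI-respiration correlation per arm, the age-adjusted
#' RMSSD ANCOVA, and the acute-outcome mixed model.
#'
#' @param daily Output of [daily_summaries()].
#' @param contrasts Output of [session_contrasts()].
#' @param subjects Subjects table (with `group`, `age_decade`, mRS
#'   columns).
#' @param config A [pipeline_config()].
#' @return A list of tibbles: `comparisons`, `equivalence`, `acute`,
#'   `correlation`, `ancova`, and `outcome_model` (an
#'   `hrv_outcome_fit`, NULL when unavailable).
#' @export
trial_stats <- function(daily, contrasts, subjects, config) {
  daily <- left_join(daily,
                     subjects[, c("subject_id", "group", "age_decade")],
                     by = "subject_id")
  changes <- filter(daily, .data$day > 1, !is.na(.data$change_from_day1))

  compare_family <- function(metrics, k) {
    rows <- list()
    for (m in metrics) {
      d <- filter(changes, .data$metric == m)
      if (nrow(d) == 0) next
      for (bin in c("all", levels(day_bin_of(1)))) {
        db <- if (bin == "all") d else filter(d, .data$day_bin == bin)
        x <- db$change_from_day1[db$group == "taVNS"]
        y <- db$change_from_day1[db$group == "Sham"]
        if (length(x) < 3 || length(y) < 3) next
        res <- compare_groups(x, y, alpha = config$alpha, bonferroni_k = k)
        rows[[length(rows) + 1L]] <- bind_cols(
          tibble(metric = m, day_bin = bin), res)
      }
    }
    list_rbind(rows)
  }
  comparisons <- bind_rows(
    mutate(compare_family(cardiac_battery, config$bonferroni_cardiac),
           family = "cardiac"),
    mutate(compare_family(vascular_battery, config$bonferroni_vascular),
           family = "vascular")
  )

  tost_one <- function(metric, margin) {
    d <- filter(changes, .data$metric == .env$metric)
    x <- d$change_from_day1[d$group == "taVNS"]
    y <- d$change_from_day1[d$group == "Sham"]
    if (length(x) < 3 || length(y) < 3) return(NULL)
    bind_cols(tibble(metric = metric),
              tost_equivalence(x, y, margin, alpha = config$alpha))
  }
  equivalence <- bind_rows(
    tost_one("hr", config$margins[["hr"]]),
    tost_one("qtc_mean", config$margins[["qt"]]),
    tost_one("bp_mean_mmHg", config$margins[["bp"]])
  )

  acute_src <- contrasts |>
    filter(.data$metric == "hr") |>
    left_join(subjects[, c("subject_id", "group")], by = "subject_id") |>
    mutate(post_minus_during = .data$z_post_minus_pre -
             .data$z_during_minus_pre)
  acute <- acute_src |>
    dplyr::group_split(.data$group) |>
    map(function(d) {
      diffs <- d$post_minus_during[!is.na(d$post_minus_during)]
      if (length(diffs[diffs != 0]) < 6) return(NULL)
      bind_cols(tibble(group = d$group[1], metric = "hr_post_minus_during"),
                signed_rank_vs_zero(diffs, alpha = config$alpha,
                                    bonferroni_k = config$bonferroni_cardiac))
    }) |>
    list_rbind()

  corr <- changes |>
    filter(.data$metric %in% c("ppi", "resp_rate_bpm")) |>
    select("subject_id", "day", "group", "metric", "change_from_day1") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = "change_from_day1") |>
    dplyr::group_split(.data$group) |>
    map(function(d) {
      if (!all(c("ppi", "resp_rate_bpm") %in% names(d))) return(NULL)
      ok <- complete.cases(d[, c("ppi", "resp_rate_bpm")])
      if (sum(ok) < 4) return(NULL)
      bind_cols(tibble(group = d$group[1]),
                pearson_with_test(d$ppi[ok], d$resp_rate_bpm[ok]))
    }) |>
    list_rbind()

  rmssd_changes <- filter(changes, .data$metric == "rmssd")
  ancova <- if (nrow(rmssd_changes) >= 6 &&
                !anyNA(rmssd_changes$age_decade)) {
    ancova_age(rename(rmssd_changes, change = "change_from_day1"),
               response = "change")
  }

  outcome <- NULL
  mm_data <- acute_src |>
    filter(!is.na(.data$z_post_minus_pre)) |>
    left_join(subjects |>
                mutate(mrs_change = .data$mrs_discharge - .data$mrs_admission) |>
                select("subject_id", "mrs_change"),
              by = "subject_id") |>
    rename(hr_change = "z_post_minus_pre")
  if (nrow(mm_data) >= 10 && length(unique(mm_data$subject_id)) >= 4) {
    outcome <- fit_outcome_model(mm_data)
  }

  list(comparisons = comparisons, equivalence = equivalence,
       acute = acute, correlation = corr, ancova = ancova,
       outcome_model = outcome)
}

#' Write pipeline artifacts
#'
#' @param result An `hrv_pipeline` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  cfg <- result$config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  existing <- list.files(dir, pattern = "\\.(csv|json)$")
  if (length(existing) > 0 && !cfg$overwrite) {
    abort("Output directory already holds artifacts; set `overwrite = TRUE`.")
  }
  wr <- function(x, f) readr::write_csv(x, file.path(dir, f))
  wr(result$cohort$subjects, "subjects.csv")
  wr(result$cohort$sessions, "sessions.csv")
  wr(result$windows, "windows.csv")
  wr(result$contrasts, "contrasts.csv")
  wr(result$daily, "daily.csv")
  st <- result$stats
  wr(bind_rows(st$comparisons,
               mutate(st$acute, family = "acute")), "results.csv")
  if (!is.null(st$equivalence) && nrow(st$equivalence) > 0) {
    wr(st$equivalence, "equivalence.csv")
  }
  if (!is.null(result$factors)) {
    jsonlite::write_json(
      list(loadings = result$factors$loadings,
           labels = result$factors$labels,
           eigenvalues = result$factors$eigenvalues,
           uniquenesses = result$factors$uniquenesses,
           rotation = result$factors$rotation,
           extraction = result$factors$extraction,
           n_obs = result$factors$n_obs),
      file.path(dir, "factors.json"), digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(st$outcome_model)) {
    jsonlite::write_json(
      list(coefficients = st$outcome_model$coefficients,
           subject_sd = st$outcome_model$subject_sd,
           residual_sd = st$outcome_model$residual_sd),
      file.path(dir, "outcome_model.json"), digits = NA, auto_unbox = TRUE)
  }
  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL
  jsonlite::write_json(
    list(package = "hrvstim",
         version = as.character(utils::packageVersion("hrvstim")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = cfg$seed,
         config_hash = rlang::hash(cfg_for_hash)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Human-readable run report
#'
#' Summarises a pipeline run in the structure of a trial results
#' section: group comparisons per metric and day bin, the acute
#' contrast tests, the factor loadings, and the equivalence battery.
#'
#' @param result An `hrv_pipeline` object from [run_pipeline()].
#' @return Character vector of report lines (invisibly); printed when
#'   interactive.
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "hrv_pipeline"))
  st <- result$stats
  ln <- c(sprintf("Cohort: %d subjects (%d taVNS / %d Sham), %d sessions",
                  nrow(result$cohort$subjects),
                  sum(result$cohort$subjects$group == "taVNS"),
                  sum(result$cohort$subjects$group == "Sham"),
                  nrow(result$cohort$sessions)),
          "")
  if (!is.null(st$comparisons) && nrow(st$comparisons) > 0) {
    ln <- c(ln, "== Daily-change group comparisons ==")
    cmp <- filter(st$comparisons, .data$day_bin == "all")
    for (i in seq_len(nrow(cmp))) {
      r <- cmp[i, ]
      verdict <- if (r$p_adjusted < result$config$alpha) "SIGNIFICANT" else "no significant difference"
      pw <- if (!is.na(r$achieved_power)) sprintf(", power(d=0.5) = %.2f", r$achieved_power) else ""
      ln <- c(ln, sprintf("  %-16s %s (%s, p_adj = %.3f, d = %+.2f%s)",
                          r$metric, verdict, r$test, r$p_adjusted,
                          r$cohens_d, pw))
    }
    ln <- c(ln, "")
  }
  if (!is.null(st$acute) && nrow(st$acute) > 0) {
    ln <- c(ln, "== Acute post-vs-during heart-rate change (vs 0) ==")
    for (i in seq_len(nrow(st$acute))) {
      r <- st$acute[i, ]
      ln <- c(ln, sprintf("  %-6s p_adj = %.3f (N = %d, d = %.2f)",
                          r$group, r$p_adjusted, r$n1, r$cohens_d))
    }
    ln <- c(ln, "")
  }
  if (!is.null(result$factors)) {
    ln <- c(ln, "== Autonomic factor loadings ==",
            utils::capture.output(print(result$factors)), "")
  }
  if (!is.null(st$equivalence) && nrow(st$equivalence) > 0) {
    ln <- c(ln, "== Equivalence (TOST) ==")
    for (i in seq_len(nrow(st$equivalence))) {
      r <- st$equivalence[i, ]
      ln <- c(ln, sprintf("  %-14s margin %4.1f: %s (p_lower = %.3g, p_upper = %.3g)",
                          r$metric, r$margin,
                          if (r$equivalent) "EQUIVALENT" else "not shown equivalent",
                          r$p_lower, r$p_upper))
    }
    ln <- c(ln, "")
  }
  if (!is.null(st$outcome_model)) {
    co <- st$outcome_model$coefficients
    r <- co[co$term == "treated_x_mrs_change", ]
    ln <- c(ln, "== Acute HR change vs outcome (mixed model) ==",
            sprintf("  treated-arm mRS slope = %.2f (p = %.3g, 95%% CI %.2f to %.2f)",
                    r$estimate, r$p_value, r$conf_low, r$conf_high), "")
  }
  if (!interactive()) {
    # returned invisibly; caller decides whether to cat
  }
  invisible(ln)
}

#' @export
print.hrv_pipeline <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
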