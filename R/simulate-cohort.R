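#' Specification of a synthetic stimulation-trial cohort
#'
#' Describes a two-arm ICU cohort receiving twice-daily 20-minute
#' stimulation sessions under continuous ECG and vitals monitoring. The
#' default arm sizes (11 active, 13 sham) and session schedule match the
#' trial design the package analyses; group-level drifts and acute
#' post-session heart-rate jumps are all injectable so that every
#' downstream estimate has a known truth.
#'
#' @param n_tavns,n_sham Subjects per arm.
#' @param days_mean,days_sd Mean and SD of the per-subject number of
#'   monitored days (clamped to 3–14).
#' @param sessions_per_day Stimulation sessions per day (default 2).
#' @param session_minutes Session length in minutes (default 20).
#' @param min_session_gap_min Minimum gap between the sessions of one
#'   day, in minutes (default 60).
#' @param day_seconds Length of the recorded day in seconds. The
#'   monitoring emulated is continuous 24-hour recording; shorter values
#'   compress the day for desk-scale experiments while keeping the
#'   session geometry valid.
#' @param mean_rr Baseline mean RR interval (s).
#' @param sdnn_ms Baseline total RR variability (ms).
#' @param lf_frac,hf_frac,resp_rate,ectopic_rate RR-process parameters,
#'   see [rr_params()].
#' @param qt_base,qt_rr_slope QT–RR coupling, see [ecg_params()].
#' @param group_effects Named list with elements `taVNS` and `Sham`, each
#'   a named vector of per-day linear drifts applied from Day 1:
#'   supported names `hr_bpm`, `qtc_ms`, `sdnn_ms`, `bp_mean_mmHg`,
#'   `ppi`, `resp_rate_bpm`, `icp_mmHg`. Defaults to all-zero drifts
#'   (a null cohort).
#' @param acute_hr_jump Mean post-minus-pre heart-rate change (bpm)
#'   injected after active-arm sessions.
#' @param mrs_slope Additional acute heart-rate change per point of mRS
#'   change (bpm) in the active arm, linking the acute biomarker to the
#'   clinical outcome; negative values mean larger HR increases in
#'   subjects whose mRS improves.
#' @param outcome_sd_subject,outcome_sd_session Between-subject and
#'   between-session SD (bpm) of the injected acute change.
#' @param ppi_resp_coupling Named vector (per arm) of correlations
#'   between daily PPI and respiration-rate offsets.
#' @param daily_offset_sd Named vector of between-day SDs for the vitals
#'   daily means.
#' @param icp_fraction Fraction of subjects with an ICP monitor.
#' @param age_decades Range of age decades sampled (inclusive, tens).
#' @param seed Integer master seed; everything derives from it.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tavns = 11, n_sham = 13, days_mean = 11,
                        days_sd = 3, sessions_per_day = 2,
                        session_minutes = 20, min_session_gap_min = 60,
                        day_seconds = 86400, mean_rr = 0.8, sdnn_ms = 40,
                        lf_frac = 0.3, hf_frac = 0.3, resp_rate = 15,
                        ectopic_rate = 0.02, qt_base = 0.40,
                        qt_rr_slope = 0.15,
                        group_effects = list(taVNS = numeric(), Sham = numeric()),
                        acute_hr_jump = 1, mrs_slope = -1.85,
                        outcome_sd_subject = 1, outcome_sd_session = 2,
                        ppi_resp_coupling = c(taVNS = -0.37, Sham = -0.08),
                        daily_offset_sd = c(bp_mean_mmHg = 4, ppi = 0.25,
                                            resp_rate_bpm = 1.5,
                                            icp_mmHg = 2),
                        icp_fraction = 0.7,
                        age_decades = c(30, 80), seed = 1L) {
  if (n_tavns < 1 || n_sham < 1) abort("Both arms need at least one subject.")
  if (sessions_per_day < 1) abort("`sessions_per_day` must be at least 1.")
  post_s <- session_minutes * 60
  need <- 0.25 * day_seconds + sessions_per_day * session_minutes * 60 +
    (sessions_per_day - 1) * min_session_gap_min * 60 + 2 * post_s
  if (day_seconds < need) {
    abort("`day_seconds` too short for the session schedule plus pre/post periods.")
  }
  structure(
    list(n_tavns = n_tavns, n_sham = n_sham, days_mean = days_mean,
         days_sd = days_sd, sessions_per_day = sessions_per_day,
         session_minutes = session_minutes,
         min_session_gap_min = min_session_gap_min,
         day_seconds = day_seconds, mean_rr = mean_rr, sdnn_ms = sdnn_ms,
         lf_frac = lf_frac, hf_frac = hf_frac, resp_rate = resp_rate,
         ectopic_rate = ectopic_rate, qt_base = qt_base,
         qt_rr_slope = qt_rr_slope, group_effects = group_effects,
         acute_hr_jump = acute_hr_jump, mrs_slope = mrs_slope,
         outcome_sd_subject = outcome_sd_subject,
         outcome_sd_session = outcome_sd_session,
         ppi_resp_coupling = ppi_resp_coupling,
         daily_offset_sd = daily_offset_sd, icp_fraction = icp_fraction,
         age_decades = age_decades, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

group_drift <- function(spec, group, key) {
  fx <- spec$group_effects[[group]]
  if (is.null(fx) || !key %in% names(fx)) 0 else fx[[key]]
}

#' Simulate the subjects table of a cohort
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `subject_id`, `group`, `age_decade`,
#'   `mrs_admission`, `mrs_discharge`, `n_days`.
#' @export
simulate_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, 1))
  n <- spec$n_tavns + spec$n_sham
  group <- sample(c(rep("taVNS", spec$n_tavns), rep("Sham", spec$n_sham)))
  decades <- seq(spec$age_decades[1], spec$age_decades[2], by = 10)
  mrs_adm <- sample(1:5, n, replace = TRUE, prob = c(0.1, 0.35, 0.2, 0.2, 0.15))
  delta <- sample(-3:2, n, replace = TRUE, prob = c(0.08, 0.2, 0.27, 0.25, 0.12, 0.08))
  tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = group,
    age_decade = sample(decades, n, replace = TRUE),
    mrs_admission = mrs_adm,
    mrs_discharge = pmin(6L, pmax(0L, mrs_adm + delta)),
    n_days = pmin(14L, pmax(3L, round(rnorm(n, spec$days_mean, spec$days_sd)))),
    has_icp = runif(n) < spec$icp_fraction
  )
}

#' Simulate the stimulation schedule for a cohort
#'
#' Places `sessions_per_day` non-overlapping sessions per subject-day
#' with at least the configured gap between them and room for a full
#' pre-period before and post-period after each session.
#'
#' @param spec A [cohort_spec()].
#' @param subjects Output of [simulate_subjects()].
#' @return A tibble `subject_id`, `day`, `session`, `onset`, `offset`
#'   (seconds within the day).
#' @export
simulate_schedule <- function(spec, subjects) {
  set.seed(derive_seed(spec$seed, 2))
  dur <- spec$session_minutes * 60
  gap <- spec$min_session_gap_min * 60
  pre <- dur
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    for (d in seq_len(subjects$n_days[i])) {
      onsets <- numeric(spec$sessions_per_day)
      base <- 0.25 * spec$day_seconds
      span <- (spec$day_seconds - 2 * dur - base) -
        (spec$sessions_per_day * dur + (spec$sessions_per_day - 1) * gap)
      jit <- runif(1, 0, max(0, min(span, 1200)))
      t0 <- base + jit
      for (k in seq_len(spec$sessions_per_day)) {
        onsets[k] <- t0
        t0 <- t0 + dur + gap
      }
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = subjects$subject_id[i], day = d,
        session = seq_len(spec$sessions_per_day),
        onset = onsets, offset = onsets + dur
      )
    }
  }
  list_rbind(rows)
}

# shared acute-outcome model: injected post-pre HR jump per session (bpm)
session_jump_model <- function(spec, subjects, schedule) {
  set.seed(derive_seed(spec$seed, 3))
  u <- rnorm(nrow(subjects), 0, spec$outcome_sd_subject)
  names(u) <- subjects$subject_id
  mrs_change <- setNames(subjects$mrs_discharge - subjects$mrs_admission,
                         subjects$subject_id)
  grp <- setNames(subjects$group, subjects$subject_id)
  sched <- arrange(schedule, .data$subject_id, .data$day, .data$session)
  g <- as.numeric(grp[sched$subject_id] == "taVNS")
  mu <- g * (spec$acute_hr_jump + spec$mrs_slope * mrs_change[sched$subject_id])
  sched$hr_jump_bpm <- mu + u[sched$subject_id] +
    rnorm(nrow(sched), 0, spec$outcome_sd_session)
  sched$mrs_change <- as.numeric(mrs_change[sched$subject_id])
  sched$group <- as.character(grp[sched$subject_id])
  sched
}

#' Simulate session-level acute outcomes only
#'
#' Fast path that skips waveform and beat generation and directly emits
#' the per-session acute heart-rate change implied by the cohort's
#' outcome model: active-arm sessions receive
#' `acute_hr_jump + mrs_slope * mrs_change` plus subject and session
#' noise; sham sessions receive noise only. Used for parameter-recovery
#' studies of the outcome model at many-replicate scale.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble `subject_id`, `group`, `mrs_change`, `day`,
#'   `session`, `hr_change` (bpm).
#' @export
simulate_session_outcomes <- function(spec) {
  subjects <- simulate_subjects(spec)
  schedule <- simulate_schedule(spec, subjects)
  out <- session_jump_model(spec, subjects, schedule)
  select(out, "subject_id", "group", "mrs_change", "day", "session",
         hr_change = "hr_jump_bpm")
}

#' Simulate the ground-truth beat table for one subject-day
#'
#' Generates the RR process for a whole recorded day (with the group's
#' daily drifts applied), attaches the per-beat true QT, and injects the
#' scheduled acute post-session heart-rate jumps.
#'
#' @param spec A [cohort_spec()].
#' @param subject One row of the subjects table.
#' @param day Day number (1-based).
#' @param day_schedule Schedule rows for this subject-day (may be empty).
#' @param hr_jumps Optional numeric vector, one injected post-session HR
#'   jump (bpm) per schedule row.
#' @return A beat tibble: `t`, `rr`, `is_ectopic`, `qt_ms`.
#' @export
simulate_subject_day <- function(spec, subject, day, day_schedule = NULL,
                                 hr_jumps = NULL) {
  drift_hr <- group_drift(spec, subject$group, "hr_bpm") * (day - 1)
  drift_qtc <- group_drift(spec, subject$group, "qtc_ms") * (day - 1)
  drift_sdnn <- group_drift(spec, subject$group, "sdnn_ms") * (day - 1)
  hr0 <- 60 / spec$mean_rr
  mean_rr_day <- 60 / (hr0 + drift_hr)
  sd_day <- max(0, spec$sdnn_ms + drift_sdnn) / 1000
  prm <- rr_params(
    mean_rr = mean_rr_day, sd_total = sd_day, lf_frac = spec$lf_frac,
    hf_frac = spec$hf_frac, resp_rate = spec$resp_rate,
    ectopic_rate = spec$ectopic_rate,
    seed = derive_seed(spec$seed, 10, sum(utf8ToInt(subject$subject_id)), day)
  )
  beats <- simulate_rr(prm, spec$day_seconds)
  qt_base_day <- spec$qt_base + drift_qtc / 1000
  beats$qt_ms <- (qt_base_day + spec$qt_rr_slope * (beats$rr - 1)) * 1000
  if (!is.null(day_schedule) && nrow(day_schedule) > 0) {
    jumps <- hr_jumps %||% rep(0, nrow(day_schedule))
    for (k in seq_len(nrow(day_schedule))) {
      beats <- apply_hr_jump(beats, jumps[k], day_schedule$offset[k],
                             day_schedule$offset[k] + 1200)
    }
  }
  select(beats, "t", "rr", "is_ectopic", "qt_ms")
}

#' Inject a heart-rate offset into a span of a beat table
#'
#' Adds `jump_bpm` to the instantaneous heart rate of every beat whose
#' time falls in `[from, to)` by shortening the RR intervals in place;
#' beat times are left untouched so session geometry is preserved.
#'
#' @param beats Beat tibble with columns `t` and `rr`.
#' @param jump_bpm Heart-rate offset (bpm).
#' @param from,to Span in seconds.
#' @return The modified beat tibble.
#' @export
apply_hr_jump <- function(beats, jump_bpm, from, to) {
  if (jump_bpm == 0) return(beats)
  idx <- beats$t >= from & beats$t < to
  beats$rr[idx] <- 60 / (60 / beats$rr[idx] + jump_bpm)
  beats
}

#' Simulate a full synthetic cohort
#'
#' Generates the subjects table, the stimulation schedule, per
#' subject-day ground-truth beat tables (with drifts and acute jumps
#' injected) and 1 Hz vitals streams. Fully reproducible from the
#' [cohort_spec()] seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given, plain-text CSV artifacts
#'   (`subjects.csv`, `sessions.csv`, `beats.csv`, `vitals.csv`) are
#'   written there.
#' @param overwrite Overwrite existing files in `dir`.
#' @param vitals Generate the 1 Hz vitals streams (can be switched off
#'   for cardiac-only experiments).
#' @param beats Generate the ground-truth beat tables (can be switched
#'   off for vitals-only experiments).
#' @return A list of class `hrv_cohort` with elements `spec`,
#'   `subjects`, `sessions`, `beats`, `vitals`.
#' @export
simulate_cohort <- function(spec, dir = NULL, overwrite = FALSE,
                            vitals = TRUE, beats = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- simulate_subjects(spec)
  schedule <- simulate_schedule(spec, subjects)
  sched <- session_jump_model(spec, subjects, schedule)

  beats_on <- beats
  beats <- list(); vit <- list()
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    cpl <- spec$ppi_resp_coupling[[subj$group]] %||% 0
    set.seed(derive_seed(spec$seed, 4, i))
    nd <- subj$n_days
    z1 <- rnorm(nd); z2 <- rnorm(nd); zb <- rnorm(nd); zi <- rnorm(nd)
    resp_off <- spec$daily_offset_sd[["resp_rate_bpm"]] * z1
    ppi_off <- spec$daily_offset_sd[["ppi"]] *
      (cpl * z1 + sqrt(max(0, 1 - cpl^2)) * z2)
    for (d in seq_len(nd)) {
      if (beats_on) {
        ds <- filter(sched, .data$subject_id == subj$subject_id, .data$day == d)
        b <- simulate_subject_day(spec, subj, d, ds, ds$hr_jump_bpm)
        b$subject_id <- subj$subject_id; b$day <- d
        beats[[length(beats) + 1L]] <- b
      }
      if (vitals) {
        means <- c(
          bp_mean_mmHg = 90 + group_drift(spec, subj$group, "bp_mean_mmHg") *
            (d - 1) + spec$daily_offset_sd[["bp_mean_mmHg"]] * zb[d],
          ppi = 1.5 + group_drift(spec, subj$group, "ppi") * (d - 1) + ppi_off[d],
          resp_rate_bpm = 16 + group_drift(spec, subj$group, "resp_rate_bpm") *
            (d - 1) + resp_off[d]
        )
        if (subj$has_icp) {
          means <- c(means, icp_mmHg = 12 +
                       group_drift(spec, subj$group, "icp_mmHg") * (d - 1) +
                       spec$daily_offset_sd[["icp_mmHg"]] * zi[d])
        }
        v <- simulate_vitals(spec$day_seconds, means = means,
                             seed = derive_seed(spec$seed, 5, i, d))
        v$subject_id <- subj$subject_id; v$day <- d
        vit[[length(vit) + 1L]] <- v
      }
    }
  }
  cohort <- structure(
    list(spec = spec, subjects = subjects,
         sessions = select(sched, "subject_id", "group", "day", "session",
                           "onset", "offset", "hr_jump_bpm", "mrs_change"),
         beats = if (beats_on) list_rbind(beats) else NULL,
         vitals = if (vitals) list_rbind(vit) else NULL),
    class = "hrv_cohort"
  )
  if (!is.null(dir)) write_cohort(cohort, dir, overwrite = overwrite)
  cohort
}

#' Write a cohort's tables as CSV artifacts
#'
#' @param cohort An `hrv_cohort`.
#' @param dir Output directory (created if absent).
#' @param overwrite Overwrite existing files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("subjects.csv", "sessions.csv", "beats.csv", "vitals.csv")
  existing <- files[file.exists(file.path(dir, files))]
  if (length(existing) > 0 && !overwrite) {
    abort(paste0("Refusing to overwrite existing files: ",
                 paste(existing, collapse = ", ")))
  }
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(cohort$sessions, file.path(dir, "sessions.csv"))
  if (!is.null(cohort$beats)) {
    readr::write_csv(cohort$beats, file.path(dir, "beats.csv"))
  }
  if (!is.null(cohort$vitals)) {
    readr::write_csv(cohort$vitals, file.path(dir, "vitals.csv"))
  }
  invisible(dir)
}

#' @export
print.hrv_cohort <- function(x, ...) {
  cat(sprintf("<hrv_cohort: %d subjects (%d taVNS / %d Sham), %d sessions, %d beats>\n",
              nrow(x$subjects), sum(x$subjects$group == "taVNS"),
              sum(x$subjects$group == "Sham"), nrow(x$sessions),
              nrow(x$beats)))
  invisible(x)
}
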