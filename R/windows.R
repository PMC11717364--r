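#' Detect stimulation sessions from the treatment-event channel
#'
#' The channel is rectified, smoothed with a 1 s moving mean and
#' binarized at half its robust maximum; rising and falling crossings
#' become session onsets and offsets. Sessions shorter than the minimum
#' duration are rejected (glitches), with a message.
#'
#' @param data Data frame with columns `t` and `event`.
#' @param fs Sampling rate of the event channel (Hz).
#' @param min_duration Minimum accepted session length (s).
#' @param robust_q Quantile used as the robust channel maximum.
#' @return A tibble of episodes: `onset`, `offset`, `duration` (s),
#'   `source`.
#' @export
detect_sessions <- function(data, fs, min_duration = 300,
                            robust_q = 0.999) {
  env <- moving_mean(abs(data$event), round(fs))
  peak <- quantile(env, robust_q, names = FALSE)
  empty <- tibble(onset = numeric(0), offset = numeric(0),
                  duration = numeric(0), source = character(0))
  if (peak <= 0) return(empty)
  thr <- peak / 2
  above <- env >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values]
  off_idx <- ends[r$values]
  onset <- data$t[on_idx]
  offset <- data$t[off_idx] + 1 / fs
  dur <- offset - onset
  short <- dur < min_duration
  if (any(short)) {
    inform(sprintf("Rejected %d sub-%g-s event pulse(s) as glitches.",
                   sum(short), min_duration))
  }
  out <- tibble(onset = onset[!short], offset = offset[!short],
                duration = dur[!short], source = "event_channel")
  if (nrow(out) == 0) empty else out
}

metric_columns <- function(data) {
  intersect(c("hr", "rmssd", "sdnn", "pnni_50", "total_power",
              "hf_power_norm", "csi", "cvi", "qt_mean", "qtc_mean",
              "prolonged_qt_frac", "sd1", "sd2"),
            names(data))
}

#' Treatment-locked and reference sliding-window metrics
#'
#' Tiles one subject-day with 6-minute windows moved in 3-minute steps:
#' reference windows cover the whole day, and for each treatment episode
#' additional windows tile the 20 min before onset (`pre`), the
#' stimulation period (`during`) and the 20 min after offset (`post`).
#' Windows whose beat coverage falls below `min_coverage` (recording
#' gaps) are dropped.
#'
#' @param beats Beat table for one subject-day (`t`, `rr`, optionally
#'   `qt_ms`, `quality`), cleaned or raw.
#' @param episodes Episodes tibble (`onset`, `offset`), e.g. from
#'   [detect_sessions()]; may be empty or NULL for reference-only.
#' @param day_start,day_end Day span in seconds (default: 0 to last
#'   beat).
#' @param window,step Window length and step (s).
#' @param pre_s,post_s Length of the pre/post periods (s).
#' @param spectral Compute frequency-domain metrics per window.
#' @param min_coverage Minimum fraction of the window covered by beats.
#' @return A tibble with `episode`, `kind`
#'   (`reference`/`pre`/`during`/`post`), `center` (s) and one column
#'   per metric.
#' @export
windowed_metrics <- function(beats, episodes = NULL, day_start = 0,
                             day_end = NULL, window = 360, step = 180,
                             pre_s = 1200, post_s = 1200, spectral = TRUE,
                             min_coverage = 0.8) {
  beats <- if ("status" %in% names(beats)) beats else clean_rr(beats)
  day_end <- day_end %||% max(beats$t)
  grids <- list()
  add_grid <- function(from, to, kind, episode) {
    if (to - from < window) return()
    starts <- seq(from, to - window, by = step)
    grids[[length(grids) + 1L]] <<- tibble(
      episode = episode, kind = kind, start = starts, center = starts + window / 2)
  }
  add_grid(day_start, day_end, "reference", NA_integer_)
  if (!is.null(episodes) && nrow(episodes) > 0) {
    for (e in seq_len(nrow(episodes))) {
      on <- episodes$onset[e]; off <- episodes$offset[e]
      add_grid(max(day_start, on - pre_s), on, "pre", e)
      add_grid(on, off, "during", e)
      add_grid(off, min(day_end, off + post_s), "post", e)
    }
  }
  grid <- bind_rows(grids)
  if (nrow(grid) == 0) {
    abort("Day too short for a single window.")
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- beats[beats$t >= grid$start[i] & beats$t < grid$start[i] + window, ]
    coverage <- sum(w$rr) / window
    if (coverage < min_coverage) next
    m <- cardiac_metrics(w, spectral = spectral, min_span = min(120, window / 2))
    rows[[i]] <- bind_cols(grid[i, c("episode", "kind", "center")], m)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    warn("All windows dropped (insufficient beat coverage).")
  }
  out
}

#' Normalize window metrics against the daily reference
#'
#' For each metric, computes z-scores against the mean and standard
#' deviation of that subject-day's reference windows. Requires at least
#' `min_ref` reference windows; metrics whose reference SD is zero get
#' `NA` z-scores.
#'
#' @param windows Output of [windowed_metrics()], optionally stacked
#'   over subject-days (grouping columns `subject_id`/`day` are
#'   respected when present).
#' @param min_ref Minimum number of reference windows per group.
#' @return The input plus one `z_<metric>` column per metric.
#' @export
normalize_daily <- function(windows, min_ref = 20) {
  mets <- metric_columns(windows)
  keys <- intersect(c("subject_id", "day"), names(windows))
  normalize_one <- function(df) {
    ref <- filter(df, .data$kind == "reference")
    for (m in mets) {
      zcol <- paste0("z_", m)
      if (nrow(ref) < min_ref) {
        df[[zcol]] <- NA_real_
        next
      }
      mu <- mean(ref[[m]], na.rm = TRUE)
      sdv <- sd(ref[[m]], na.rm = TRUE)
      df[[zcol]] <- if (is.na(sdv) || sdv == 0) NA_real_ else (df[[m]] - mu) / sdv
    }
    df
  }
  if (length(keys) == 0) return(normalize_one(windows))
  windows |>
    group_by(across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ normalize_one(.x)) |>
    ungroup()
}

#' Per-session pre/during/post contrasts
#'
#' Averages each metric over the windows of each period of each episode
#' and forms the during-minus-pre and post-minus-pre differences, in raw
#' and (when present) daily-z units.
#'
#' @param windows Output of [normalize_daily()] (or [windowed_metrics()]
#'   for raw-only contrasts).
#' @return A long tibble: grouping keys, `episode`, `metric`,
#'   `during_minus_pre`, `post_minus_pre`, `z_during_minus_pre`,
#'   `z_post_minus_pre` (NA when a period had no valid window).
#' @export
session_contrasts <- function(windows) {
  keys <- intersect(c("subject_id", "day"), names(windows))
  mets <- metric_columns(windows)
  zmets <- intersect(paste0("z_", mets), names(windows))
  per <- windows |>
    filter(.data$kind %in% c("pre", "during", "post")) |>
    group_by(across(dplyr::all_of(c(keys, "episode", "kind")))) |>
    summarise(across(dplyr::all_of(c(mets, zmets)), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  long <- per |>
    tidyr::pivot_longer(dplyr::all_of(c(mets, zmets)),
                        names_to = "metric", values_to = "value") |>
    mutate(scale = if_else(startsWith(.data$metric, "z_"), "z", "raw"),
           metric = sub("^z_", "", .data$metric)) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  for (col in c("pre", "during", "post")) {
    if (!col %in% names(long)) long[[col]] <- NA_real_
  }
  long <- long |>
    mutate(during_minus_pre = .data$during - .data$pre,
           post_minus_pre = .data$post - .data$pre) |>
    select(dplyr::all_of(c(keys, "episode", "metric", "scale")),
           "during_minus_pre", "post_minus_pre") |>
    tidyr::pivot_wider(names_from = "scale",
                       values_from = c("during_minus_pre", "post_minus_pre"),
                       names_glue = "{ifelse(scale == 'z', 'z_', '')}{.value}")
  long
}

#' Daily 24-hour summaries with change from Day 1 and 3-day bins
#'
#' Aggregates cardiac metrics (and, when supplied, vitals means) over
#' each subject-day, anchors every metric to its Day 1 value and assigns
#' the 3-day bins used for phase-wise group comparisons (days 2–4, 5–7,
#' 8–10, 11–13).
#'
#' @param beats Cohort beat table (`subject_id`, `day`, `t`, `rr`, ...).
#' @param vitals Optional cohort vitals table (`subject_id`, `day`,
#'   vitals columns); streams that are all-`NA` for a subject-day are
#'   skipped.
#' @param spectral Include frequency-domain metrics.
#' @return A long tibble: `subject_id`, `day`, `metric`, `value`,
#'   `change_from_day1` (NA when the subject lacks Day 1), `day_bin`.
#' @export
daily_summaries <- function(beats, vitals = NULL, spectral = FALSE) {
  stopifnot(all(c("subject_id", "day") %in% names(beats)))
  daily <- beats |>
    group_by(.data$subject_id, .data$day) |>
    dplyr::group_modify(~ cardiac_metrics(.x, spectral = spectral)) |>
    ungroup()
  mets <- metric_columns(daily)
  long <- tidyr::pivot_longer(daily[, c("subject_id", "day", mets)],
                              dplyr::all_of(mets),
                              names_to = "metric", values_to = "value")
  if (!is.null(vitals)) {
    vcols <- intersect(c("bp_mean_mmHg", "ppi", "resp_rate_bpm",
                         "icp_mmHg", "abp_mmHg"), names(vitals))
    vlong <- vitals |>
      group_by(.data$subject_id, .data$day) |>
      summarise(across(dplyr::all_of(vcols), ~ mean(.x, na.rm = TRUE)),
                .groups = "drop") |>
      tidyr::pivot_longer(dplyr::all_of(vcols), names_to = "metric",
                          values_to = "value") |>
      filter(!is.nan(.data$value))
    long <- bind_rows(long, vlong)
  }
  missing_d1 <- long |>
    group_by(.data$subject_id) |>
    summarise(has_d1 = any(.data$day == 1), .groups = "drop")
  if (any(!missing_d1$has_d1)) {
    inform(sprintf("%d subject(s) lack Day 1; their changes are NA.",
                   sum(!missing_d1$has_d1)))
  }
  long |>
    group_by(.data$subject_id, .data$metric) |>
    mutate(change_from_day1 = .data$value -
             .data$value[match(1, .data$day)]) |>
    ungroup() |>
    mutate(day_bin = day_bin_of(.data$day))
}

#' Assign the 3-day phase bin of a day number
#' @param day Integer day (1-based from first hospitalized day).
#' @return Factor with levels `D2_4`, `D5_7`, `D8_10`, `D11_13` (NA for
#'   day 1 or beyond day 13).
#' @export
day_bin_of <- function(day) {
  cut(day, breaks = c(1.5, 4.5, 7.5, 10.5, 13.5),
      labels = c("D2_4", "D5_7", "D8_10", "D11_13"))
}
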