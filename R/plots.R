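#' Treatment-locked course of a normalized metric
#'
#' Plots the mean daily-z value of a metric in the pre/during/post
#' windows against time from treatment onset, by group when available.
#'
#' @param windows Output of [normalize_daily()] joined (optionally) with
#'   a `group` column; rows of kind `reference` are ignored.
#' @param sessions Session table with `subject_id`, `day`, `onset` used
#'   to express window centers relative to onset.
#' @param metric Metric name (default `"hr"`).
#' @return A ggplot object.
#' @export
plot_session_course <- function(windows, sessions, metric = "hr") {
  zcol <- paste0("z_", metric)
  if (!zcol %in% names(windows)) abort(sprintf("No column `%s`.", zcol))
  d <- windows |>
    filter(.data$kind != "reference", !is.na(.data$episode)) |>
    left_join(sessions |>
                mutate(episode = as.integer(.data$session)) |>
                select("subject_id", "day", "episode", "onset", "group"),
              by = c("subject_id", "day", "episode")) |>
    mutate(rel_min = (.data$center - .data$onset) / 60,
           rel_bin = round(.data$rel_min / 3) * 3) |>
    group_by(.data$group, .data$rel_bin) |>
    summarise(mean_z = mean(.data[[zcol]], na.rm = TRUE),
              se_z = sd(.data[[zcol]], na.rm = TRUE) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$rel_bin, .data$mean_z,
                                  colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_z - .data$se_z,
                                      ymax = .data$mean_z + .data$se_z,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "minutes from treatment onset",
                  y = sprintf("daily-z %s", metric), colour = "group",
                  fill = "group")
}

#' Daily changes from Day 1 by phase bin and group
#'
#' @param daily Output of [daily_summaries()].
#' @param subjects Subjects table carrying `group`.
#' @param metric Metric name.
#' @return A ggplot object.
#' @export
plot_daily_changes <- function(daily, subjects, metric = "hr") {
  d <- daily |>
    filter(.data$metric == !!metric, !is.na(.data$day_bin),
           !is.na(.data$change_from_day1)) |>
    left_join(subjects[, c("subject_id", "group")], by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$day_bin, .data$change_from_day1,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = sprintf("change in %s from Day 1", metric),
                  fill = "group")
}
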