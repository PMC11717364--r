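#' Simulate a treatment-event channel
#'
#' Renders the stimulation marker channel as rectangular pulses, one per
#' scheduled session. By default the pulse alternates sign at 2 Hz (as a
#' stimulator drive signal would), which is why downstream session
#' detection rectifies before binarizing at the half-maximum.
#'
#' @param schedule A data frame with columns `onset` and `offset`
#'   (seconds); sessions must not overlap.
#' @param duration Channel length in seconds.
#' @param fs Sampling rate in Hz.
#' @param amplitude Pulse amplitude (arbitrary units).
#' @param noise_sd Additive white noise standard deviation, same units.
#' @param alternating Alternate pulse sign at 2 Hz instead of a constant
#'   level.
#' @param seed Integer seed for the noise.
#'
#' @return A tibble with columns `t` and `event`, carrying the true
#'   schedule in the `truth` attribute.
#' @export
simulate_event_channel <- function(schedule, duration, fs = 500,
                                   amplitude = 1, noise_sd = 0,
                                   alternating = TRUE, seed = 1L) {
  schedule <- as_tibble(schedule)
  if (nrow(schedule) > 0) {
    if (!all(c("onset", "offset") %in% names(schedule))) {
      abort("`schedule` must have columns `onset` and `offset`.")
    }
    schedule <- arrange(schedule, .data$onset)
    if (any(schedule$offset <= schedule$onset)) {
      abort("Each session must have `offset` > `onset`.")
    }
    if (nrow(schedule) > 1 &&
        any(schedule$onset[-1] < schedule$offset[-nrow(schedule)])) {
      abort("Sessions overlap; the schedule must be non-overlapping.")
    }
  }
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  ev <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    idx <- tt >= schedule$onset[i] & tt < schedule$offset[i]
    ev[idx] <- if (alternating) {
      amplitude * sign(sin(2 * pi * 2 * tt[idx]) + 1e-12)
    } else {
      amplitude
    }
  }
  set.seed(seed)
  if (noise_sd > 0) ev <- ev + rnorm(n, 0, noise_sd)
  out <- tibble(t = tt, event = ev)
  attr(out, "truth") <- schedule
  out
}
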