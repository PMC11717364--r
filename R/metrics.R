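#' Clean an RR-interval series into normal-to-normal intervals
#'
#' Applies the physiological acceptance rules in order: intervals longer
#' than 2 s or shorter than 300 ms are excluded as out of range, then
#' intervals differing by more than 20% from the previous *kept*
#' interval are excluded as ectopic. Comparing against the previous kept
#' interval (rather than the previous raw one) prevents a single outlier
#' from cascading exclusions.
#'
#' @param data A data frame with columns `rr` (seconds) and optionally
#'   `t` (interval end time, seconds); extra columns pass through.
#' @param rr_max,rr_min Range filter bounds in seconds.
#' @param rel_diff Relative-difference threshold for the ectopic rule
#'   (strictly greater than; the default 0.2 keeps an exactly-20% step).
#'
#' @return The input with a `status` column
#'   (`kept`/`too_long`/`too_short`/`ectopic`).
#' @export
clean_rr <- function(data, rr_max = 2, rr_min = 0.3, rel_diff = 0.2) {
  data <- as_tibble(data)
  if (!"rr" %in% names(data)) abort("`data` must have an `rr` column.")
  n <- nrow(data)
  status <- rep("kept", n)
  if (n == 0) {
    data$status <- character(0)
    return(data)
  }
  if (any(data$rr <= 0, na.rm = TRUE)) abort("RR intervals must be positive.")
  status[data$rr > rr_max] <- "too_long"
  status[data$rr < rr_min] <- "too_short"
  prev_kept <- NA_real_
  for (i in seq_len(n)) {
    if (status[i] != "kept") next
    if (!is.na(prev_kept) &&
        abs(data$rr[i] - prev_kept) / prev_kept > rel_diff) {
      status[i] <- "ectopic"
    } else {
      prev_kept <- data$rr[i]
    }
  }
  data$status <- status
  data
}

kept_rr <- function(data) {
  if (!"status" %in% names(data)) data <- clean_rr(data)
  filter(data, .data$status == "kept")
}

# successive kept pairs that were adjacent in the raw series
successive_diffs <- function(data) {
  if (!"status" %in% names(data)) data <- clean_rr(data)
  keep <- data$status == "kept"
  idx <- which(keep)
  if (length(idx) < 2) return(numeric(0))
  adj <- diff(idx) == 1
  (data$rr[idx[-1]] - data$rr[idx[-length(idx)]])[adj]
}

#' Time-domain heart-rate-variability metrics
#'
#' Standard Task-Force definitions over the kept (normal-to-normal)
#' intervals: mean heart rate, RMSSD, SDNN (sample SD, N−1 denominator)
#' and pNNI-50 (percentage of successive differences strictly exceeding
#' 50 ms). Successive differences only count pairs that were adjacent in
#' the raw series.
#'
#' @param data An RR data frame (cleaned with [clean_rr()], or raw — it
#'   is cleaned on the fly).
#' @return A one-row tibble: `hr` (bpm), `rmssd` (ms), `sdnn` (ms),
#'   `pnni_50` (%), `n_kept`, plus `reason_null` naming the first metric
#'   precondition that failed (NA when all were computable).
#' @export
hrv_time <- function(data) {
  data <- if ("status" %in% names(data)) data else clean_rr(data)
  rr <- kept_rr(data)$rr
  d <- successive_diffs(data)
  reason <- NA_character_
  hr <- if (length(rr) >= 1) 60 / mean(rr) else NA_real_
  sdnn <- if (length(rr) >= 2) sd(rr) * 1000 else NA_real_
  if (length(rr) < 2) reason <- "fewer than 2 kept intervals"
  if (length(d) >= 1) {
    rmssd <- sqrt(mean((d * 1000)^2))
    pnni_50 <- 100 * mean(abs(d * 1000) > 50)
  } else {
    rmssd <- NA_real_
    pnni_50 <- NA_real_
    reason <- reason %|na|% "no successive kept pairs"
  }
  tibble(hr = hr, rmssd = rmssd, sdnn = sdnn, pnni_50 = pnni_50,
         n_kept = length(rr), reason_null = reason)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Frequency-domain heart-rate-variability metrics
#'
#' The kept-interval tachogram is resampled to an even grid by cubic
#' interpolation and its periodogram integrated: total power over
#' (f_lo, 0.4] Hz (f_lo = 1/window span) and the high-frequency
#' (0.15–0.4 Hz) fraction of it.
#'
#' @param data An RR data frame with `t` and `rr` (cleaned or raw).
#' @param resample_hz Tachogram resampling rate (Hz).
#' @param hf_band,f_max High-frequency band and total-power upper edge
#'   (Hz).
#' @param min_span Minimum kept-interval span in seconds.
#' @return A one-row tibble: `total_power` (ms^2), `hf_power_norm`
#'   (unitless in \[0,1\]), `reason_null`.
#' @export
hrv_frequency <- function(data, resample_hz = 4, hf_band = c(0.15, 0.4),
                          f_max = 0.4, min_span = 120) {
  data <- if ("status" %in% names(data)) data else clean_rr(data)
  if (!"t" %in% names(data)) abort("`data` must have a `t` column for spectral metrics.")
  k <- kept_rr(data)
  nul <- tibble(total_power = NA_real_, hf_power_norm = NA_real_,
                reason_null = "window span below minimum")
  if (nrow(k) < 4) return(mutate(nul, reason_null = "fewer than 4 kept intervals"))
  span <- max(k$t) - min(k$t)
  if (span < min_span) return(nul)
  grid <- seq(min(k$t), max(k$t), by = 1 / resample_hz)
  x <- spline(k$t, k$rr * 1000, xout = grid)$y
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(fft(x))^2 / n          # periodogram, two-sided
  freq <- (seq_len(n) - 1) * resample_hz / n
  half <- freq > 0 & freq <= resample_hz / 2
  df <- resample_hz / n
  p <- sp[half] / resample_hz      # power spectral density (ms^2 / Hz)
  f <- freq[half]
  f_lo <- 1 / span
  tot_idx <- f > f_lo & f <= f_max
  hf_idx <- f > hf_band[1] & f <= hf_band[2]
  total <- 2 * sum(p[tot_idx]) * df
  hf <- 2 * sum(p[hf_idx & tot_idx]) * df
  tibble(total_power = total,
         hf_power_norm = if (total > 0) hf / total else NA_real_,
         reason_null = NA_character_)
}

#' Poincare-plot autonomic indices
#'
#' Short- and long-axis dispersions of the Poincare plot computed from
#' successive kept pairs, and the derived cardiac sympathetic index
#' (CSI = SD2/SD1) and cardiac vagal index
#' (CVI = log10(SD1 * SD2 * 16)), after Toichi's L/T formulation.
#'
#' @param data An RR data frame (cleaned or raw).
#' @param min_pairs Minimum number of successive kept pairs.
#' @return A one-row tibble: `sd1`, `sd2` (ms), `csi`, `cvi`,
#'   `reason_null`.
#' @export
hrv_poincare <- function(data, min_pairs = 10) {
  data <- if ("status" %in% names(data)) data else clean_rr(data)
  d <- successive_diffs(data) * 1000
  rr <- kept_rr(data)$rr * 1000
  if (length(d) < min_pairs) {
    return(tibble(sd1 = NA_real_, sd2 = NA_real_, csi = NA_real_,
                  cvi = NA_real_, reason_null = "too few successive pairs"))
  }
  sd1 <- sqrt(var(d) / 2)
  sd2_sq <- 2 * var(rr) - var(d) / 2
  sd2 <- sqrt(max(0, sd2_sq))
  csi <- if (sd1 > 0) sd2 / sd1 else NA_real_
  cvi <- if (sd1 > 0 && sd2 > 0) log10(sd1 * sd2 * 16) else NA_real_
  tibble(sd1 = sd1, sd2 = sd2, csi = csi, cvi = cvi,
         reason_null = if (sd1 > 0) NA_character_ else "zero short-axis dispersion")
}

#' QT and Bazett-corrected QT metrics
#'
#' Per-beat QTc = QT / sqrt(RR) (QT and RR in seconds, result in ms),
#' which standardizes the QT interval to a 60 bpm heart rate. Beats are
#' eligible when their delineation quality is `ok` and the preceding RR
#' interval was kept by [clean_rr()]. Prolonged repolarization is scored
#' as the percentage of eligible beats with QTc at or above 500 ms.
#'
#' @param data A beat data frame with columns `qt_ms`, `rr` (s), and
#'   optionally `status` (RR cleaning) and `quality` (delineation).
#' @param prolonged_ms Prolonged-QTc threshold (ms, inclusive).
#' @return A one-row tibble: `qt_mean`, `qt_median`, `qtc_mean`,
#'   `qtc_median` (ms), `prolonged_qt_frac` (%), `n_beats`,
#'   `reason_null`.
#' @export
qt_metrics <- function(data, prolonged_ms = 500) {
  data <- as_tibble(data)
  if (!all(c("qt_ms", "rr") %in% names(data))) {
    abort("`data` must have `qt_ms` and `rr` columns.")
  }
  elig <- !is.na(data$qt_ms) & !is.na(data$rr)
  if ("quality" %in% names(data)) elig <- elig & data$quality == "ok"
  if ("status" %in% names(data)) elig <- elig & data$status == "kept"
  qt <- data$qt_ms[elig]
  rr <- data$rr[elig]
  if (length(qt) == 0) {
    return(tibble(qt_mean = NA_real_, qt_median = NA_real_,
                  qtc_mean = NA_real_, qtc_median = NA_real_,
                  prolonged_qt_frac = NA_real_, n_beats = 0L,
                  reason_null = "no eligible beats"))
  }
  qtc <- qt / sqrt(rr)
  tibble(qt_mean = mean(qt), qt_median = median(qt),
         qtc_mean = mean(qtc), qtc_median = median(qtc),
         prolonged_qt_frac = 100 * mean(qtc >= prolonged_ms),
         n_beats = length(qt), reason_null = NA_character_)
}

#' All cardiac metrics for one beat window
#'
#' Convenience wrapper binding [hrv_time()], [hrv_poincare()],
#' [qt_metrics()] and (optionally) [hrv_frequency()] into one row.
#'
#' @param data A beat data frame with `t`, `rr`, and optionally `qt_ms`,
#'   `quality`.
#' @param spectral Include frequency-domain metrics (needs a span of at
#'   least `min_span` s).
#' @param min_span Passed to [hrv_frequency()].
#' @return A one-row tibble of metrics.
#' @export
cardiac_metrics <- function(data, spectral = TRUE, min_span = 120) {
  data <- if ("status" %in% names(data)) data else clean_rr(data)
  out <- bind_cols(
    select(hrv_time(data), -"reason_null"),
    select(hrv_poincare(data), -"reason_null", -"sd1", -"sd2")
  )
  if (spectral) {
    out <- bind_cols(out, select(hrv_frequency(data, min_span = min_span),
                                 -"reason_null"))
  }
  if ("qt_ms" %in% names(data)) {
    out <- bind_cols(out, select(qt_metrics(data), -"reason_null",
                                 -"qt_median", -"qtc_median", -"n_beats"))
  }
  out
}
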