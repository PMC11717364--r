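#' Detect R peaks from the gradient of the ECG
#'
#' QRS complexes are located from the steepness of the absolute gradient
#' of the signal: the rectified first difference is smoothed into an
#' envelope, candidate complexes are envelope maxima above an adaptive
#' threshold, and the R peak is refined as the extremum of the
#' (baseline-removed) ECG inside each candidate window. Working on the
#' gradient magnitude makes detection robust to lead polarity.
#'
#' @param record A preprocessed `ecg_record` (see [ecg_preprocess()]).
#' @param fs Sampling rate in Hz; defaults to the record's attribute.
#' @param min_rr Refractory period in seconds (default 0.25 s,
#'   i.e. 240 bpm ceiling).
#' @param threshold_frac Fraction of the local (2 s rolling) envelope
#'   maximum a candidate must exceed.
#'
#' @return A tibble with `r_peak` (1-based sample index) and `t`
#'   (seconds). Detections inside gap spans are suppressed.
#' @export
detect_r_peaks <- function(record, fs = record_fs(record), min_rr = 0.25,
                           threshold_frac = 0.35) {
  x <- record$ecg
  n <- length(x)
  if (n < 2 * fs) {
    warn("Record shorter than two beats; returning no detections.")
    return(tibble(r_peak = integer(0), t = numeric(0)))
  }
  # confine the gradient to the QRS energy band so broadband noise does
  # not swamp the slope envelope
  lp <- signal::butter(4, min(25, 0.45 * fs / 2) / (fs / 2), type = "low")
  xs <- signal::filtfilt(lp, x)
  grad <- abs(c(0, diff(xs))) * fs
  env <- moving_mean(grad, round(0.12 * fs))
  # adaptive threshold: fraction of the envelope's local maximum level
  win <- as.integer(2 * fs)
  k <- ceiling(n / win)
  blocks <- rep(seq_len(k), each = win)[seq_len(n)]
  block_max <- tapply(env, blocks, max)
  # smooth block maxima so an empty block does not drop the floor
  level <- pmax(block_max, 0.3 * max(block_max))
  thr <- (threshold_frac * level)[blocks]
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr[cand]]
  if (length(cand) == 0) return(tibble(r_peak = integer(0), t = numeric(0)))

  # enforce refractory period, keeping the stronger envelope peak
  keep <- integer(0)
  last <- -Inf
  ord <- cand
  for (i in ord) {
    if ((i - last) / fs >= min_rr) {
      keep <- c(keep, i)
      last <- i
    } else if (length(keep) > 0 && env[i] > env[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }

  # refine to the ECG extremum (dominant polarity) near the envelope peak
  half <- as.integer(round(0.06 * fs))
  r <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    seg <- x[lo:hi]
    lo + which.max(abs(seg)) - 1L
  }, integer(1))
  r <- sort(unique(r))
  if ("gap" %in% names(record) && any(record$gap)) {
    r <- r[!record$gap[r]]
  }
  tibble(r_peak = r, t = (r - 1) / fs)
}
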