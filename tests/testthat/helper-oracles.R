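# independent brute-force oracles, deliberately written as plain loops so
# they share no code with the implementation they check

rmssd_brute <- function(rr_ms) {
  s <- 0; k <- 0
  for (i in 2:length(rr_ms)) {
    s <- s + (rr_ms[i] - rr_ms[i - 1])^2
    k <- k + 1
  }
  sqrt(s / k)
}

sdnn_brute <- function(rr_ms) {
  m <- sum(rr_ms) / length(rr_ms)
  sqrt(sum((rr_ms - m)^2) / (length(rr_ms) - 1))
}

pnni50_brute <- function(rr_ms) {
  k <- 0; hits <- 0
  for (i in 2:length(rr_ms)) {
    k <- k + 1
    if (abs(rr_ms[i] - rr_ms[i - 1]) > 50) hits <- hits + 1
  }
  100 * hits / k
}

prolonged_frac_brute <- function(qtc_ms) {
  n <- 0
  for (v in qtc_ms) if (v >= 500) n <- n + 1
  100 * n / length(qtc_ms)
}

# band-power fractions of an unevenly sampled tachogram, via linear
# interpolation and a raw periodogram (independent of hrv_frequency)
band_fraction_oracle <- function(t, rr_s, band = c(0.15, 0.4), f_max = 0.4,
                                 fs = 4) {
  grid <- seq(min(t), max(t), by = 1 / fs)
  x <- approx(t, rr_s, xout = grid)$y
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 1 / diff(range(t)) & f <= f_max
  hf <- f > band[1] & f <= band[2] & keep
  sum(sp[hf]) / sum(sp[keep])
}

# match detections to truth at a tolerance; returns sensitivity/ppv/f1
match_peaks <- function(truth, detected, tol) {
  tp <- sum(vapply(truth, function(r) any(abs(detected - r) <= tol), logical(1)))
  fn <- length(truth) - tp
  fp <- sum(vapply(detected, function(r) !any(abs(truth - r) <= tol), logical(1)))
  c(sens = tp / (tp + fn), ppv = tp / (tp + fp),
    f1 = 2 * tp / (2 * tp + fp + fn))
}

# small synthetic subject-day defaults used across window tests
test_spec <- function(...) {
  cohort_spec(n_tavns = 2, n_sham = 2, days_mean = 3, days_sd = 0,
              day_seconds = 14400, ...)
}
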