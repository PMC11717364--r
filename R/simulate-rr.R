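#' Parameters for the synthetic RR-interval process
#'
#' The RR series is modelled as a mean interval plus two sinusoidal
#' modulations — a low-frequency oscillation at 0.1 Hz (Mayer-wave band)
#' and a respiratory oscillation at `resp_rate / 60` Hz — with randomized
#' phases and a white Gaussian remainder. The sinusoid amplitudes are set
#' so that `lf_frac` and `hf_frac` of the total RR variance
#' (`sd_total^2`) fall in the corresponding bands, which makes band-power
#' fractions of the generated tachogram directly assertable.
#'
#' @param mean_rr Mean RR interval in seconds; must lie in `[0.3, 2]` s,
#'   the physiological acceptance band applied downstream.
#' @param sd_total Target overall RR standard deviation in seconds
#'   (i.e. the ground-truth SDNN).
#' @param lf_frac,hf_frac Fractions of total RR variance placed at 0.1 Hz
#'   and at the respiratory frequency; their sum must not exceed 1. The
#'   remainder is white noise.
#' @param resp_rate Respiration rate in breaths per minute.
#' @param ectopic_rate Fraction of beats replaced by premature (ectopic)
#'   beats, in `[0, 0.2]`. Each injected ectopic shortens the interval by
#'   25–40% of the preceding interval, so it always violates the 20%
#'   relative-difference rule used by [clean_rr()].
#' @param gaps List of `c(start, duration)` pairs (seconds) describing
#'   recording dropouts; beats inside a gap are dropped and the span is
#'   reported in the `gaps` attribute.
#' @param seed Integer seed; the process is fully reproducible from it.
#'
#' @return A list of class `rr_params`.
#' @seealso [simulate_rr()]
#' @export
rr_params <- function(mean_rr = 0.8, sd_total = 0.04, lf_frac = 0.3,
                      hf_frac = 0.3, resp_rate = 15, ectopic_rate = 0,
                      gaps = list(), seed = 1L) {
  if (mean_rr < 0.3 || mean_rr > 2) {
    abort("`mean_rr` must lie in [0.3, 2] seconds.")
  }
  if (sd_total < 0) abort("`sd_total` must be non-negative.")
  if (lf_frac < 0 || hf_frac < 0 || lf_frac + hf_frac > 1) {
    abort("`lf_frac` and `hf_frac` must be non-negative and sum to at most 1.")
  }
  if (ectopic_rate < 0 || ectopic_rate > 0.2) {
    abort("`ectopic_rate` must lie in [0, 0.2].")
  }
  if (resp_rate <= 0) abort("`resp_rate` must be positive.")
  structure(
    list(mean_rr = mean_rr, sd_total = sd_total, lf_frac = lf_frac,
         hf_frac = hf_frac, resp_rate = resp_rate,
         ectopic_rate = ectopic_rate, gaps = gaps, seed = as.integer(seed)),
    class = "rr_params"
  )
}

#' Simulate a ground-truth RR-interval series
#'
#' Generates beat times and RR intervals from an [rr_params()] process.
#' Ectopic beats are flagged in the output so every downstream cleaning
#' rule has an oracle; recording gaps remove the beats they cover.
#'
#' @param params An [rr_params()] object.
#' @param duration Length of the series in seconds; must be at least ten
#'   mean RR intervals.
#'
#' @return A tibble with one row per emitted beat: `beat` (index), `t`
#'   (beat time, seconds), `rr` (preceding interval, seconds) and
#'   `is_ectopic`. The modulation signal used (before ectopic injection)
#'   is kept in the `modulation` column for spectral ground truth.
#' @export
simulate_rr <- function(params, duration) {
  stopifnot(inherits(params, "rr_params"))
  if (duration < 10 * params$mean_rr) {
    abort("`duration` must cover at least 10 mean RR intervals.")
  }
  set.seed(params$seed)
  n_max <- ceiling(duration / params$mean_rr * 1.6) + 20L
  a_lf <- params$sd_total * sqrt(2 * params$lf_frac)
  a_hf <- params$sd_total * sqrt(2 * params$hf_frac)
  sd_white <- params$sd_total * sqrt(max(0, 1 - params$lf_frac - params$hf_frac))
  phi <- runif(2, 0, 2 * pi)
  f_hf <- params$resp_rate / 60

  white <- rnorm(n_max, 0, sd_white)
  ect <- runif(n_max) < params$ectopic_rate
  ect_mag <- runif(n_max, 0.25, 0.40)

  t <- numeric(n_max); rr <- numeric(n_max); mod <- numeric(n_max)
  is_ect <- logical(n_max)
  t_cur <- 0; i <- 0L
  while (t_cur < duration && i < n_max) {
    i <- i + 1L
    mod[i] <- a_lf * sin(2 * pi * 0.1 * t_cur + phi[1]) +
      a_hf * sin(2 * pi * f_hf * t_cur + phi[2]) + white[i]
    rr_i <- params$mean_rr + mod[i]
    rr_i <- min(max(rr_i, 0.25), 2.5)
    if (i > 1L && ect[i]) {
      # premature beat: >20% shorter than the preceding emitted interval
      rr_i <- rr[i - 1L] * (1 - ect_mag[i])
      is_ect[i] <- TRUE
    }
    t_cur <- t_cur + rr_i
    t[i] <- t_cur
    rr[i] <- rr_i
  }
  out <- tibble(
    beat = seq_len(i), t = t[seq_len(i)], rr = rr[seq_len(i)],
    modulation = mod[seq_len(i)], is_ectopic = is_ect[seq_len(i)]
  )
  out <- filter(out, .data$t <= duration)
  for (g in params$gaps) {
    out <- filter(out, .data$t < g[1] | .data$t > g[1] + g[2])
  }
  attr(out, "params") <- params
  out
}
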