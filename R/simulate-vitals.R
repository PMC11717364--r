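#' Simulate one subject-day of 1 Hz vital-sign streams
#'
#' Produces mean blood pressure, plethysmography perfusion index (PPI),
#' respiration rate and (optionally) intracranial pressure and
#' arterial-line blood pressure as slowly wandering AR(1) processes
#' around the supplied daily means.
#'
#' @param n_seconds Stream length in seconds (one sample per second).
#' @param means Named numeric vector of daily means: `bp_mean_mmHg`,
#'   `ppi`, `resp_rate_bpm`, and optionally `icp_mmHg`, `abp_mmHg`.
#'   Omitting `icp_mmHg`/`abp_mmHg` omits the stream (all-`NA` column),
#'   mirroring monitoring lines that were not placed.
#' @param wander_sd Named vector of within-day standard deviations; any
#'   stream not named falls back to 5% of its mean.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `timestamp_s`, `bp_mean_mmHg`, `ppi`,
#'   `resp_rate_bpm`, `icp_mmHg`, `abp_mmHg`.
#' @export
simulate_vitals <- function(n_seconds,
                            means = c(bp_mean_mmHg = 90, ppi = 1.5,
                                      resp_rate_bpm = 16, icp_mmHg = 12),
                            wander_sd = NULL, seed = 1L) {
  set.seed(seed)
  n <- as.integer(n_seconds)
  ar1 <- function(n, sd, phi = 0.999) {
    e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive"))
  }
  stream <- function(key) {
    if (!key %in% names(means)) return(rep(NA_real_, n))
    sdv <- if (!is.null(wander_sd) && key %in% names(wander_sd)) {
      wander_sd[[key]]
    } else {
      abs(means[[key]]) * 0.05
    }
    means[[key]] + ar1(n, sdv)
  }
  tibble(
    timestamp_s = seq_len(n) - 1,
    bp_mean_mmHg = stream("bp_mean_mmHg"),
    ppi = stream("ppi"),
    resp_rate_bpm = stream("resp_rate_bpm"),
    icp_mmHg = stream("icp_mmHg"),
    abp_mmHg = stream("abp_mmHg")
  )
}
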