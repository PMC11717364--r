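#' Parameters for synthetic ECG morphology
#'
#' Each beat is rendered as a sum of five Gaussians (P, Q, R, S, T) in
#' textbook lead II proportions, in the spirit of the classic ECGSYN
#' generator. The per-beat QT interval follows a linear QT–RR coupling,
#' `QT = qt_base + qt_rr_slope * (RR - 1)`, and the T-wave Gaussian is
#' placed so that the ground-truth T offset lands exactly at
#' `QRS onset + QT`.
#'
#' Ground-truth fiducials are defined geometrically: QRS onset/offset sit
#' 2.5 standard deviations outside the Q and S Gaussian centres, and the
#' T offset sits where the descending T limb decays to the delineator's
#' default offset criterion (2.33 standard deviations past the T peak).
#'
#' @param fs Sampling rate in Hz (default 500).
#' @param qt_base QT interval at RR = 1 s, in seconds.
#' @param qt_rr_slope Linear QT–RR slope (seconds per second). Setting
#'   `qt_rr_slope` so that the true Bazett-corrected QT is constant turns
#'   QTc invariance into an assertable oracle.
#' @param amplitudes,widths,offsets Named numeric vectors (`p`, `q`, `r`,
#'   `s`, and for `amplitudes`/`widths` also `t`) giving Gaussian
#'   amplitude (mV), standard deviation (s) and centre offset from the R
#'   peak (s). The T-wave centre is derived from the QT interval.
#' @param noise_sd Additive white noise standard deviation in mV.
#' @param powerline_amp Amplitude of 60 Hz powerline interference in mV.
#'
#' @return A list of class `ecg_params`.
#' @export
ecg_params <- function(fs = 500, qt_base = 0.40, qt_rr_slope = 0.15,
                       amplitudes = c(p = 0.15, q = -0.10, r = 1.0,
                                      s = -0.25, t = 0.35),
                       widths = c(p = 0.022, q = 0.010, r = 0.012,
                                  s = 0.010, t = 0.050),
                       offsets = c(p = -0.18, q = -0.035, s = 0.035),
                       noise_sd = 0, powerline_amp = 0) {
  if (fs < 250) abort("`fs` must be at least 250 Hz.")
  need <- c("p", "q", "r", "s", "t")
  if (!all(need %in% names(amplitudes)) || !all(need %in% names(widths)) ||
      !all(c("p", "q", "s") %in% names(offsets))) {
    abort("`amplitudes`, `widths` and `offsets` must name the component waves.")
  }
  structure(
    list(fs = fs, qt_base = qt_base, qt_rr_slope = qt_rr_slope,
         amplitudes = amplitudes, widths = widths, offsets = offsets,
         noise_sd = noise_sd, powerline_amp = powerline_amp),
    class = "ecg_params"
  )
}

# offset criterion used both by the truth convention and the delineator:
# a Gaussian-derivative limb falls to 25% of its extremum 2.33 sd past it
.t_off_k <- 2.33

#' Render a synthetic ECG record from ground-truth beats
#'
#' Produces a continuous lead-II-like trace with one P-QRS-T complex per
#' beat, and ships the aligned per-beat fiducial ground truth so every
#' delineation stage can be scored against it.
#'
#' @param beats A tibble from [simulate_rr()] (columns `t`, `rr`,
#'   `is_ectopic`).
#' @param params An [ecg_params()] object.
#' @param gaps Optional list of `c(start, duration)` spans (seconds)
#'   zero-filled and masked as recording dropouts.
#' @param seed Integer seed for the additive noise.
#'
#' @return A tibble of class `ecg_record` with columns `t`, `ecg` (mV)
#'   and `gap`, carrying attributes `fs` and `truth` (per-beat fiducials
#'   in 1-based sample indices plus `true_qt_ms` and `is_ectopic`).
#' @export
simulate_ecg <- function(beats, params = ecg_params(), gaps = list(),
                         seed = 1L) {
  stopifnot(inherits(params, "ecg_params"))
  if (!all(c("t", "rr") %in% names(beats))) {
    abort("`beats` must have columns `t` and `rr`.")
  }
  fs <- params$fs
  amp <- params$amplitudes; wd <- params$widths; off <- params$offsets
  rr_min <- min(beats$rr)
  qt_min <- params$qt_base + params$qt_rr_slope * (rr_min - 1)
  if (qt_min <= 0) abort("QT-RR coupling yields non-positive QT at the shortest RR.")

  qrs_on_off <- off[["q"]] - 2.5 * wd[["q"]]
  qrs_off_off <- off[["s"]] + 2.5 * wd[["s"]]
  # adjacent complexes must not overlap: T must end before the next QRS onset
  # (at high heart rates the next P may ride on the T tail, as in real ECG)
  if (qrs_on_off + qt_min + 0.01 > rr_min + qrs_on_off) {
    abort("Wave parameters produce overlapping adjacent complexes at the shortest RR.")
  }

  duration <- max(beats$t) + 0.6
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  ecg <- numeric(n)

  qt <- params$qt_base + params$qt_rr_slope * (beats$rr - 1)
  t_r <- beats$t
  # atrial and repolarization geometry compresses with the cycle length,
  # as in ECGSYN-style generators
  rate_scale <- sqrt(pmin(pmax(beats$rr, 0.3), 2))
  sig_p <- wd[["p"]] * rate_scale
  sig_t <- wd[["t"]] * rate_scale
  centers <- list(
    p = t_r + off[["p"]] * rate_scale,
    q = t_r + off[["q"]],
    r = t_r,
    s = t_r + off[["s"]],
    t = t_r + qrs_on_off + qt - .t_off_k * sig_t
  )
  sigmas <- list(p = sig_p, q = rep(wd[["q"]], length(t_r)),
                 r = rep(wd[["r"]], length(t_r)),
                 s = rep(wd[["s"]], length(t_r)), t = sig_t)
  for (w in names(centers)) {
    cw <- centers[[w]]; aw <- amp[[w]]; sws <- sigmas[[w]]
    for (i in seq_along(cw)) {
      sw <- sws[i]
      lo <- max(1L, floor((cw[i] - 4 * sw) * fs) + 1L)
      hi <- min(n, ceiling((cw[i] + 4 * sw) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      ecg[idx] <- ecg[idx] + aw * exp(-((tt[idx] - cw[i])^2) / (2 * sw^2))
    }
  }
  set.seed(seed)
  if (params$noise_sd > 0) ecg <- ecg + rnorm(n, 0, params$noise_sd)
  if (params$powerline_amp > 0) {
    ecg <- ecg + params$powerline_amp * sin(2 * pi * 60 * tt)
  }
  gap <- rep(FALSE, n)
  for (g in gaps) {
    idx <- tt >= g[1] & tt < g[1] + g[2]
    gap[idx] <- TRUE
    ecg[idx] <- 0
  }

  to_sample <- function(x) as.integer(round(x * fs)) + 1L
  truth <- tibble(
    beat = seq_along(t_r),
    p_on = to_sample(centers$p - 2.5 * sig_p),
    p_peak = to_sample(centers$p),
    p_off = to_sample(centers$p + 2.5 * sig_p),
    qrs_on = to_sample(t_r + qrs_on_off),
    r_peak = to_sample(t_r),
    qrs_off = to_sample(t_r + qrs_off_off),
    t_peak = to_sample(centers$t),
    t_off = to_sample(t_r + qrs_on_off + qt),
    true_qt_ms = qt * 1000,
    is_ectopic = if ("is_ectopic" %in% names(beats)) beats$is_ectopic else FALSE
  )
  new_ecg_record(tibble(t = tt, ecg = ecg, gap = gap), fs = fs, truth = truth)
}

new_ecg_record <- function(data, fs, truth = NULL) {
  out <- as_tibble(data)
  attr(out, "fs") <- fs
  attr(out, "truth") <- truth
  class(out) <- c("ecg_record", class(out))
  out
}

#' Sampling rate of an ECG record
#' @param record An `ecg_record`, or any tibble with an `fs` attribute.
#' @return Sampling rate in Hz.
#' @export
record_fs <- function(record) {
  fs <- attr(record, "fs", exact = TRUE)
  if (is.null(fs)) abort("`record` carries no `fs` attribute; pass `fs` explicitly.")
  fs
}

#' @export
print.ecg_record <- function(x, ...) {
  fs <- attr(x, "fs", exact = TRUE)
  cat(sprintf("<ecg_record: %d samples at %g Hz (%.1f s), %d gap samples>\n",
              nrow(x), fs, nrow(x) / fs, sum(x$gap)))
  NextMethod()
}
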