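#' Delineate P, QRS and T waves around detected R peaks
#'
#' Wave boundaries are taken from the dyadic wavelet transform of the
#' ECG. The QRS complex is found from the modulus-maxima pair the R wave
#' creates; its onset is where the transform modulus, walked backwards
#' from the first modulus maximum before that pair, falls below a
#' fraction of it (offset symmetrically). The T wave is sought as a
#' modulus-maxima pair at a coarser scale in a search window after the
#' QRS offset, and its offset is the point where the post-peak modulus
#' decays below `t_off_frac` of the descending-limb maximum. Unresolvable
#' waves are flagged, never guessed.
#'
#' @param record Preprocessed `ecg_record`.
#' @param r_peaks Output of [detect_r_peaks()] (tibble with `r_peak`).
#' @param fs Sampling rate (Hz).
#' @param qrs_scale,t_scale,p_scale Dyadic scale indices (j for 2^j)
#'   used for the QRS and for the smoother T/P waves.
#' @param qrs_bound_frac Fraction of the flanking modulus maximum at
#'   which the QRS onset/offset is placed.
#' @param t_off_frac Fraction of the post-peak modulus maximum at which
#'   the T offset is placed.
#' @param t_noise_frac T/P-wave acceptance threshold as a fraction of the
#'   RMS of the transform over a 2 s context around the beat.
#'
#' @return A tibble of per-beat annotations: sample indices `p_on`,
#'   `p_peak`, `p_off`, `qrs_on`, `r_peak`, `qrs_off`, `t_peak`, `t_off`
#'   (NA where unresolved), `qt_ms`, and `quality` (`ok`, `no_t`, `no_p`,
#'   `edge`).
#' @export
delineate_waves <- function(record, r_peaks, fs = record_fs(record),
                            qrs_scale = 3, t_scale = 4, p_scale = 4,
                            qrs_bound_frac = 0.3, t_off_frac = 0.25,
                            t_noise_frac = 0.25) {
  r <- r_peaks$r_peak
  x <- record$ecg
  n <- length(x)
  if (length(r) == 0) {
    return(tibble(beat = integer(0), p_on = integer(0), p_peak = integer(0),
                  p_off = integer(0), qrs_on = integer(0), r_peak = integer(0),
                  qrs_off = integer(0), t_peak = integer(0), t_off = integer(0),
                  qt_ms = numeric(0), quality = character(0)))
  }
  W <- ecg_wavelet(x, scales = sort(unique(c(qrs_scale, t_scale, p_scale))))
  wq <- W[, paste0("w", qrs_scale)]
  wt <- W[, paste0("w", t_scale)]
  wp <- W[, paste0("w", p_scale)]

  rr <- diff(r) / fs
  rr_of <- c(rr[1], rr)  # preceding RR per beat (first borrows the next)

  out <- vector("list", length(r))
  for (b in seq_along(r)) {
    ri <- r[b]
    ann <- list(beat = b, p_on = NA_integer_, p_peak = NA_integer_,
                p_off = NA_integer_, qrs_on = NA_integer_, r_peak = ri,
                qrs_off = NA_integer_, t_peak = NA_integer_,
                t_off = NA_integer_, qt_ms = NA_real_, quality = "ok")
    rr_b <- rr_of[b]
    t_win_end_s <- max(0.4, 0.6 * rr_b)
    # a full complex plus T search window must fit inside the record
    if (ri - 0.30 * fs < 1 || ri + (0.08 + t_win_end_s) * fs > n) {
      ann$quality <- "edge"
      out[[b]] <- ann
      next
    }
    qrs <- qrs_bounds(wq, ri, fs, qrs_bound_frac)
    if (is.null(qrs)) {
      ann$quality <- "edge"
      out[[b]] <- ann
      next
    }
    ann$qrs_on <- qrs$on; ann$qrs_off <- qrs$off

    # context noise level for accepting low-amplitude waves
    ctx <- max(1L, ri - fs):min(n, ri + fs)
    noise_t <- t_noise_frac * sqrt(mean(wt[ctx]^2))

    # T wave: search after QRS offset, clipped before the next QRS; at
    # short cycle lengths the T peak crowds the QRS, so the search start
    # tightens with RR
    lo <- qrs$off + as.integer(round(min(0.08, 0.12 * rr_b) * fs))
    hi <- qrs$off + as.integer(round(t_win_end_s * fs))
    if (b < length(r)) hi <- min(hi, r[b + 1] - as.integer(round(0.16 * fs)))
    tw <- wave_bounds(wt, lo, hi, noise_t, t_off_frac, t_off_frac,
                      max_sep = as.integer(round(0.15 * fs)),
                      smooth = as.integer(round(0.02 * fs)))
    if (is.null(tw)) {
      ann$quality <- "no_t"
    } else {
      ann$t_peak <- tw$peak; ann$t_off <- tw$off
      ann$qt_ms <- (tw$off - qrs$on) / fs * 1000
    }

    # P wave: search before QRS onset
    plo <- qrs$on - as.integer(round(0.28 * fs))
    phi <- qrs$on - as.integer(round(0.03 * fs))
    if (b > 1) plo <- max(plo, r[b - 1] + as.integer(round(0.15 * fs)))
    noise_p <- t_noise_frac * sqrt(mean(wp[ctx]^2))
    pw <- wave_bounds(wp, plo, phi, noise_p, 0.25, 0.25,
                      max_sep = as.integer(round(0.10 * fs)),
                      smooth = as.integer(round(0.02 * fs)))
    if (is.null(pw)) {
      if (ann$quality == "ok") ann$quality <- "no_p"
    } else {
      ann$p_on <- pw$on; ann$p_peak <- pw$peak; ann$p_off <- pw$off
    }

    if ("gap" %in% names(record) && any(record$gap)) {
      span_lo <- max(1L, min(c(ann$p_on, ann$qrs_on), na.rm = TRUE))
      span_hi <- min(n, max(c(ann$qrs_off, ann$t_off), na.rm = TRUE))
      if (any(record$gap[span_lo:span_hi])) ann$quality <- "edge"
    }
    out[[b]] <- ann
  }
  ann <- bind_rows(out)
  ann$quality <- as.character(ann$quality)
  ann
}

# QRS onset/offset from the modulus-maxima pair around the R peak
qrs_bounds <- function(w, ri, fs, bound_frac) {
  n <- length(w)
  rad <- as.integer(round(0.08 * fs))
  pre_win <- max(1L, ri - rad):ri
  post_win <- ri:min(n, ri + rad)
  aw <- abs(w)
  pre_mm <- pre_win[local_maxima(aw[pre_win])]
  post_mm <- post_win[local_maxima(aw[post_win])]
  if (length(pre_mm) == 0 || length(post_mm) == 0) return(NULL)
  main_pre <- pre_mm[which.max(aw[pre_mm])]
  main_post <- post_mm[which.max(aw[post_mm])]

  # first modulus maximum before the pair: the Q limb sits immediately
  # before the R upstroke, so only the nearest maximum within 50 ms
  # qualifies (anything farther is the P wave or T tail)
  ext <- max(1L, main_pre - as.integer(round(0.05 * fs))):main_pre
  cand <- ext[local_maxima(aw[ext])]
  cand <- cand[aw[cand] >= 0.04 * aw[main_pre]]
  first_mm <- if (length(cand) > 0) max(cand) else main_pre

  thr_on <- bound_frac * aw[first_mm]
  i <- first_mm
  lim <- max(1L, first_mm - as.integer(round(0.06 * fs)))
  while (i > lim && aw[i] > thr_on) i <- i - 1L
  on <- i

  ext2 <- main_post:min(n, main_post + as.integer(round(0.05 * fs)))
  cand2 <- ext2[local_maxima(aw[ext2])]
  cand2 <- cand2[aw[cand2] >= 0.1 * aw[main_post]]
  last_mm <- if (length(cand2) > 0) min(cand2) else main_post
  thr_off <- bound_frac * aw[last_mm]
  i <- last_mm
  lim <- min(n, last_mm + as.integer(round(0.06 * fs)))
  while (i < lim && aw[i] > thr_off) i <- i + 1L
  list(on = as.integer(on), off = as.integer(i))
}

# generic smooth-wave bounds: modulus-maxima pair inside [lo, hi]
wave_bounds <- function(w, lo, hi, noise, on_frac, off_frac,
                        max_sep = Inf, smooth = 1L) {
  n <- length(w)
  lo <- max(1L, as.integer(lo)); hi <- min(n, as.integer(hi))
  if (hi - lo < 5) return(NULL)
  win <- lo:hi
  aw <- abs(w)
  # boundary walks use a lightly smoothed modulus so broadband noise does
  # not trip the threshold crossing early
  aw_s <- if (smooth > 1L) moving_mean(aw, smooth) else aw
  mm <- win[local_maxima(aw[win])]
  mm <- mm[aw[mm] > noise]
  if (length(mm) < 1) return(NULL)
  main <- mm[which.max(aw[mm])]
  # the paired opposite-sign maximum defines the other limb; it must sit
  # within a plausible wave width of the main limb, else the response is
  # treated as monophasic (guards against pairing with a neighbour wave)
  opp <- mm[sign(w[mm]) != sign(w[main]) & abs(mm - main) <= max_sep]
  first_mm <- main; last_mm <- main; peak <- main
  if (length(opp) > 0) {
    pair <- opp[which.max(aw[opp])]
    a <- min(main, pair); bnd <- max(main, pair)
    zc <- which(diff(sign(w[a:bnd])) != 0)
    peak <- if (length(zc) > 0) a + zc[1] else as.integer((a + bnd) / 2)
    last_mm <- bnd
    first_mm <- a
  }

  hold <- max(1L, as.integer(smooth))
  thr_off <- off_frac * aw[last_mm]
  lim <- min(n, hi + as.integer(0.1 * (hi - lo)))
  off <- sustained_crossing(aw_s, last_mm, lim, thr_off, hold)

  thr_on <- on_frac * aw[first_mm]
  lim2 <- max(1L, lo - as.integer(0.1 * (hi - lo)))
  on <- sustained_crossing(aw_s, first_mm, lim2, thr_on, hold)
  list(on = as.integer(on), peak = as.integer(peak), off = as.integer(off))
}


# first index (walking from `from` towards `to`) where `x` stays at or
# below `thr` for `hold` consecutive samples; returns the boundary index
sustained_crossing <- function(x, from, to, thr, hold = 1L) {
  idx <- if (to >= from) from:to else from:to
  below <- x[idx] <= thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= hold)
  if (length(hit) == 0) return(idx[length(idx)])
  idx[starts[hit[1]]]
}
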