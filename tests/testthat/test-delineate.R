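make_record <- function(hr = 75, dur = 60, noise_sd = 0, seed = 1,
                        sd_frac = 0.02, powerline = 0, qtc = 0.40) {
  rr <- 60 / hr
  b <- simulate_rr(rr_params(mean_rr = rr, sd_total = sd_frac * rr,
                             seed = seed), dur)
  simulate_ecg(b, ecg_params(qt_base = qtc * sqrt(rr), qt_rr_slope = 0,
                             noise_sd = noise_sd,
                             powerline_amp = powerline), seed = seed)
}

test_that("preprocessing removes DC, powerline and keeps fiducial bands", {
  fs <- 500
  tt <- (0:(20 * fs - 1)) / fs
  dc <- hrvstim:::new_ecg_record(
    tibble::tibble(t = tt, ecg = rep(0.7, length(tt)),
                   gap = FALSE), fs = fs)
  out <- ecg_preprocess(dc)
  expect_lt(mean(abs(out$ecg[(5 * fs):(15 * fs)])), 1e-6)

  band_power <- function(x, f0, fs, bw = 1) {
    n <- length(x)
    sp <- Mod(fft(x - mean(x)))^2
    f <- (seq_len(n) - 1) * fs / n
    sum(sp[f >= f0 - bw & f <= f0 + bw])
  }
  pl <- hrvstim:::new_ecg_record(
    tibble::tibble(t = tt, ecg = sin(2 * pi * 60 * tt), gap = FALSE), fs = fs)
  filtered <- ecg_preprocess(pl)
  expect_lt(band_power(filtered$ecg, 60, fs) / band_power(pl$ecg, 60, fs),
            0.05)

  s1 <- hrvstim:::new_ecg_record(
    tibble::tibble(t = tt, ecg = sin(2 * pi * 1 * tt), gap = FALSE), fs = fs)
  f1 <- ecg_preprocess(s1)
  mid <- (5 * fs):(15 * fs)
  atten_db <- 20 * log10(sd(f1$ecg[mid]) / sd(s1$ecg[mid]))
  expect_gt(atten_db, -3)

  expect_error(ecg_preprocess(dc, fs = 100), "125")
})

test_that("preprocessing is idempotent and dilates gap masks", {
  rec <- make_record(dur = 30)
  once <- ecg_preprocess(rec)
  twice <- ecg_preprocess(once)
  # a second pass only re-attenuates band-edge energy: the passband
  # response of the 0.5 Hz fifth-order Butterworth deviates from unity
  # by ~1e-4 at the beat fundamental, so exact idempotence is bounded by
  # the filter response, not by arithmetic precision
  n <- nrow(once)
  mid <- round(0.1 * n):round(0.9 * n)
  expect_lt(max(abs(once$ecg[mid] - twice$ecg[mid])) / max(abs(once$ecg)),
            0.01)

  b <- simulate_rr(rr_params(seed = 1), 40)
  gappy <- simulate_ecg(b, gaps = list(c(15, 5)))
  out <- ecg_preprocess(gappy)
  # mask grows by about 1 s on each side
  expect_true(all(out$gap[out$t > 14.2 & out$t < 20.8]))
  expect_false(any(out$gap[out$t < 13.5 | out$t > 21.5]))
})

test_that("R-peak detection is sensitive, precise and polarity-robust", {
  rec <- make_record(hr = 75, dur = 480, seed = 2)   # ~600 beats
  tr <- attr(rec, "truth")
  rp <- detect_r_peaks(ecg_preprocess(rec))
  m <- match_peaks(tr$r_peak, rp$r_peak, tol = 0.04 * 500)
  expect_gte(m["sens"], 0.99)
  expect_gte(m["ppv"], 0.99)

  inv <- rec
  inv$ecg <- -inv$ecg
  rp_inv <- detect_r_peaks(ecg_preprocess(inv))
  expect_equal(nrow(rp_inv), nrow(rp))

  flat <- hrvstim:::new_ecg_record(
    tibble::tibble(t = (0:14999) / 500, ecg = rep(0, 15000), gap = FALSE),
    fs = 500)
  expect_equal(nrow(detect_r_peaks(flat)), 0)

  short <- hrvstim:::new_ecg_record(
    tibble::tibble(t = (0:499) / 500, ecg = rnorm(500, 0, 0.01),
                   gap = FALSE), fs = 500)
  expect_warning(detect_r_peaks(short), "shorter")
})

test_that("wave delineation recovers QT against the ground-truth sidecar", {
  rec <- make_record(hr = 75, dur = 120, seed = 3)
  tr <- attr(rec, "truth")
  pp <- ecg_preprocess(rec)
  ann <- delineate_waves(pp, detect_r_peaks(pp))
  ix <- vapply(ann$r_peak, function(r) which.min(abs(tr$r_peak - r)),
               integer(1))
  err <- ann$qt_ms - tr$true_qt_ms[ix]
  expect_lte(median(abs(err), na.rm = TRUE), 10)

  # ordering invariant on every emitted beat
  for (i in seq_len(nrow(ann))) {
    v <- unlist(ann[i, c("p_on", "p_peak", "p_off", "qrs_on", "r_peak",
                         "qrs_off", "t_peak", "t_off")])
    v <- v[!is.na(v)]
    expect_true(all(diff(v) >= 0))
  }
  expect_true(all(diff(ann$r_peak) > 0))
})

test_that("missing T waves and truncated beats are flagged, not guessed", {
  b <- simulate_rr(rr_params(mean_rr = 0.8, sd_total = 0, seed = 1), 30)
  no_t <- simulate_ecg(b, ecg_params(
    amplitudes = c(p = 0.15, q = -0.10, r = 1.0, s = -0.25, t = 0),
    qt_rr_slope = 0))
  pp <- ecg_preprocess(no_t)
  ann <- delineate_waves(pp, detect_r_peaks(pp))
  mid <- ann[ann$quality != "edge", ]
  expect_true(all(mid$quality == "no_t"))
  expect_true(all(is.na(mid$qt_ms)))

  rec <- make_record(dur = 30)
  # truncate the record just after the last R peak so its T wave is cut
  tr <- attr(rec, "truth")
  cut <- tr$r_peak[nrow(tr)] + 25
  rec2 <- hrvstim:::new_ecg_record(rec[seq_len(cut), ], fs = 500)
  pp2 <- ecg_preprocess(rec2)
  ann2 <- delineate_waves(pp2, detect_r_peaks(pp2))
  expect_equal(ann2$quality[nrow(ann2)], "edge")
  expect_true(is.na(ann2$qt_ms[nrow(ann2)]))
})

test_that("detections and annotations respect gap masks", {
  b <- simulate_rr(rr_params(mean_rr = 0.8, sd_total = 0, seed = 4), 60)
  rec <- simulate_ecg(b, gaps = list(c(20, 10)))
  pp <- ecg_preprocess(rec)
  rp <- detect_r_peaks(pp)
  expect_false(any(rp$t > 20 & rp$t < 30))
  ann <- delineate_waves(pp, rp)
  ann_t <- (ann$r_peak - 1) / 500
  near_gap <- ann[ann_t > 18.8 & ann_t < 31.2, ]
  # beats whose waves touch the dilated gap are flagged
  expect_true(all(near_gap$quality != "ok"))
})
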