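test_that("RR process honours zero-variance and validation contracts", {
  p <- rr_params(mean_rr = 0.8, sd_total = 0, ectopic_rate = 0, seed = 1)
  b <- simulate_rr(p, 60)
  expect_true(all(abs(b$rr - 0.8) < 1e-12))
  m <- hrv_time(clean_rr(b))
  expect_equal(m$rmssd, 0)
  expect_equal(m$sdnn, 0)

  expect_error(rr_params(lf_frac = 0.6, hf_frac = 0.5), "sum to at most 1")
  expect_error(rr_params(mean_rr = 0.2), "0.3")
  expect_error(simulate_rr(rr_params(), 5), "at least 10")
})

test_that("RR spectral power lands in the configured bands", {
  p <- rr_params(mean_rr = 0.8, sd_total = 0.05, lf_frac = 0.0,
                 hf_frac = 0.9, resp_rate = 15, seed = 3)
  b <- simulate_rr(p, 600)
  frac <- band_fraction_oracle(b$t, b$rr)
  expect_gte(frac, 0.8)

  p2 <- rr_params(mean_rr = 0.8, sd_total = 0.05, lf_frac = 0.9,
                  hf_frac = 0.0, seed = 3)
  b2 <- simulate_rr(p2, 600)
  expect_lte(band_fraction_oracle(b2$t, b2$rr), 0.2)
})

test_that("ectopic injection matches its rate and breaks the 20% rule", {
  total <- 0L
  for (s in 1:10) {
    p <- rr_params(mean_rr = 0.8, sd_total = 0.02, ectopic_rate = 0.05,
                   seed = s)
    b <- simulate_rr(p, 1000 * 0.8 + 10)
    b <- b[seq_len(min(nrow(b), 1000)), ]
    total <- total + sum(b$is_ectopic)
    # every injected ectopic violates the relative-difference rule
    idx <- which(b$is_ectopic)
    idx <- idx[idx > 1]
    rel <- abs(b$rr[idx] - b$rr[idx - 1]) / b$rr[idx - 1]
    expect_true(all(rel > 0.2))
  }
  ci <- qbinom(c(0.005, 0.995), 10 * 1000, 0.05)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("RR generation is deterministic under a fixed seed", {
  p <- rr_params(sd_total = 0.05, ectopic_rate = 0.03, seed = 11)
  expect_identical(simulate_rr(p, 120), simulate_rr(p, 120))
})

test_that("gap schedules drop the beats they cover", {
  p <- rr_params(sd_total = 0, gaps = list(c(30, 10)), seed = 1)
  b <- simulate_rr(p, 120)
  expect_false(any(b$t >= 30 & b$t <= 40))
})

test_that("rendered ECG carries exact per-beat ground truth", {
  p <- rr_params(mean_rr = 1.0, sd_total = 0, seed = 1)
  b <- simulate_rr(p, 12)
  rec <- simulate_ecg(b, ecg_params(qt_base = 0.40, qt_rr_slope = 0))
  tr <- attr(rec, "truth")
  expect_true(all(abs(tr$true_qt_ms - 400) < 1e-9))
  # R-peak truth coincides with the rendered maxima
  for (i in seq_len(nrow(tr))) {
    win <- (tr$r_peak[i] - 5):(tr$r_peak[i] + 5)
    expect_lte(abs(which.max(rec$ecg[win]) + win[1] - 1 - tr$r_peak[i]), 1)
  }
  # fiducial ordering
  expect_true(all(tr$p_on < tr$p_peak & tr$p_peak < tr$p_off &
                    tr$p_off <= tr$qrs_on & tr$qrs_on < tr$r_peak &
                    tr$r_peak < tr$qrs_off & tr$qrs_off < tr$t_peak &
                    tr$t_peak < tr$t_off))
})

test_that("overlapping complexes are rejected at validation", {
  p <- rr_params(mean_rr = 0.4, sd_total = 0, seed = 1)
  b <- simulate_rr(p, 10)
  expect_error(
    simulate_ecg(b, ecg_params(qt_base = 0.45, qt_rr_slope = 0)),
    "overlapping"
  )
})

test_that("event channel renders and validates schedules", {
  sched <- tibble::tibble(onset = 100, offset = 100 + 1200)
  ev <- simulate_event_channel(sched, duration = 1600, fs = 50,
                               noise_sd = 0)
  ses <- detect_sessions(ev, fs = 50)
  expect_equal(nrow(ses), 1)
  expect_lt(abs(ses$onset - 100), 1.1)
  expect_lt(abs(ses$offset - 1300), 1.1)

  ev2 <- simulate_event_channel(sched, duration = 1600, fs = 50,
                                noise_sd = 0.1, seed = 4)
  ses2 <- detect_sessions(ev2, fs = 50)
  expect_equal(nrow(ses2), 1)
  expect_lt(abs(ses2$onset - 100), 2)

  empty <- simulate_event_channel(tibble::tibble(onset = numeric(0),
                                                 offset = numeric(0)),
                                  duration = 100, fs = 50)
  expect_true(all(empty$event == 0))
  expect_equal(nrow(detect_sessions(empty, fs = 50)), 0)

  overlap <- tibble::tibble(onset = c(0, 500), offset = c(600, 1100))
  expect_error(simulate_event_channel(overlap, 1200, fs = 10), "overlap")
})

test_that("cohort generator reproduces the trial shape deterministically", {
  spec <- test_spec()
  subj <- simulate_subjects(cohort_spec(n_tavns = 11, n_sham = 13))
  expect_equal(nrow(subj), 24)
  expect_equal(sum(subj$group == "taVNS"), 11)
  expect_equal(sum(subj$group == "Sham"), 13)

  co1 <- simulate_cohort(spec, vitals = FALSE)
  co2 <- simulate_cohort(spec, vitals = FALSE)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$beats, co2$beats)

  # schedule invariants: two sessions, non-overlapping, >= 60 min apart
  s <- co1$sessions
  by_day <- split(s, interaction(s$subject_id, s$day))
  for (d in by_day) {
    expect_equal(nrow(d), 2)
    expect_gte(d$onset[2] - d$offset[1], 3600)
    expect_true(all(abs((d$offset - d$onset) - 1200) < 1e-9))
  }
})

test_that("cohort CSV artifacts round-trip and respect overwrite", {
  dir <- withr::local_tempdir()
  spec <- test_spec()
  co <- simulate_cohort(spec, dir = dir)
  expect_error(write_cohort(co, dir), "overwrite")
  back <- read_cohort(dir)
  expect_equal(nrow(back$subjects), nrow(co$subjects))
  expect_equal(back$beats$rr, co$beats$rr, tolerance = 1e-12)
})

test_that("vitals streams carry daily coupling and optional ICP", {
  v <- simulate_vitals(600, means = c(bp_mean_mmHg = 90, ppi = 1.5,
                                      resp_rate_bpm = 16), seed = 2)
  expect_true(all(is.na(v$icp_mmHg)))
  expect_false(anyNA(v$bp_mean_mmHg))

  # negative PPI-respiration coupling visible in daily offsets
  spec <- cohort_spec(n_tavns = 5, n_sham = 5, days_mean = 12, days_sd = 0,
                      day_seconds = 14400,
                      ppi_resp_coupling = c(taVNS = -0.6, Sham = -0.6),
                      seed = 5)
  co <- simulate_cohort(spec, beats = FALSE)
  daily <- co$vitals |>
    dplyr::group_by(subject_id, day) |>
    dplyr::summarise(ppi = mean(ppi), resp = mean(resp_rate_bpm),
                     .groups = "drop") |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(d_ppi = ppi - ppi[day == 1],
                  d_resp = resp - resp[day == 1]) |>
    dplyr::filter(day > 1)
  ct <- pearson_with_test(daily$d_ppi, daily$d_resp)
  expect_lt(ct$r, 0)
  expect_lt(ct$p_value, 0.05)
})

test_that("session outcome fast path embodies the interaction model", {
  spec <- cohort_spec(n_tavns = 12, n_sham = 12, days_mean = 10,
                      days_sd = 2, acute_hr_jump = 1, mrs_slope = -1.85,
                      seed = 21)
  out <- simulate_session_outcomes(spec)
  expect_true(all(c("subject_id", "group", "mrs_change", "hr_change") %in%
                    names(out)))
  # sham sessions carry no mRS dependence by construction
  sham <- out[out$group == "Sham", ]
  fit <- lm(hr_change ~ mrs_change, data = sham)
  expect_gt(summary(fit)$coefficients["mrs_change", 4], 0.01)
})

test_that("waveform records round-trip through their plain-text format", {
  dir <- withr::local_tempdir()
  b <- simulate_rr(rr_params(seed = 3), 20)
  rec <- simulate_ecg(b)
  pfx <- file.path(dir, "s01_d01")
  write_record(rec, pfx)
  expect_error(write_record(rec, pfx), "overwrite")
  back <- read_record(pfx)
  expect_equal(record_fs(back), 500)
  expect_equal(back$ecg, rec$ecg, tolerance = 1e-12)
  tr <- attr(back, "truth")
  expect_equal(tr$beat_sample, attr(rec, "truth")$r_peak)
  expect_true(all(c("qrs_on", "t_off", "true_qt_ms", "is_ectopic") %in%
                    names(tr)))
  # the restored record feeds straight back into the pipeline
  ann <- delineate_waves(ecg_preprocess(back), detect_r_peaks(ecg_preprocess(back)))
  expect_gt(nrow(ann), 10)
})
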