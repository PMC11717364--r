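test_that("RR cleaning applies the range and ectopic rules in order", {
  r1 <- clean_rr(tibble::tibble(rr = c(0.80, 2.10, 0.81)))
  expect_equal(r1$status, c("kept", "too_long", "kept"))

  r2 <- clean_rr(tibble::tibble(rr = c(0.80, 1.00)))
  expect_equal(r2$status, c("kept", "ectopic"))

  # exactly 20% is kept (rule is strictly greater)
  r3 <- clean_rr(tibble::tibble(rr = c(0.80, 0.96)))
  expect_equal(r3$status, c("kept", "kept"))

  r4 <- clean_rr(tibble::tibble(rr = c(0.25, 0.80)))
  expect_equal(r4$status, c("too_short", "kept"))

  # comparison against the previous KEPT interval stops cascades
  r5 <- clean_rr(tibble::tibble(rr = c(0.80, 0.50, 0.82)))
  expect_equal(r5$status, c("kept", "ectopic", "kept"))

  expect_equal(nrow(clean_rr(tibble::tibble(rr = numeric(0)))), 0)
})

test_that("exclusion ledger is complete over random series", {
  set.seed(42)
  for (i in 1:20) {
    rr <- runif(200, 0.25, 2.2)
    cl <- clean_rr(tibble::tibble(rr = rr))
    expect_equal(sum(table(cl$status)), 200)
    expect_setequal(unique(cl$status),
                    intersect(c("kept", "too_long", "too_short", "ectopic"),
                              unique(cl$status)))
    kept <- cl$rr[cl$status == "kept"]
    expect_true(all(kept >= 0.3 & kept <= 2))
  }
})

test_that("time-domain metrics match their definitions and oracle", {
  const <- clean_rr(tibble::tibble(rr = rep(0.8, 20)))
  m <- hrv_time(const)
  expect_equal(m$rmssd, 0)
  expect_equal(m$sdnn, 0)
  expect_equal(m$pnni_50, 0)
  expect_equal(m$hr, 75)

  alt <- clean_rr(tibble::tibble(rr = rep(c(0.800, 0.850), 10)))
  ma <- hrv_time(alt)
  expect_equal(ma$rmssd, 50)
  expect_equal(ma$pnni_50, 0)  # 50 ms is not > 50 ms

  set.seed(7)
  for (i in 1:50) {
    n <- sample(50:400, 1)
    rr <- runif(n, 0.75, 0.88)  # inside range, below the 20% step
    m <- hrv_time(clean_rr(tibble::tibble(rr = rr)))
    rr_ms <- rr * 1000
    expect_equal(m$rmssd, rmssd_brute(rr_ms), tolerance = 1e-9)
    expect_equal(m$sdnn, sdnn_brute(rr_ms), tolerance = 1e-9)
    expect_equal(m$pnni_50, pnni50_brute(rr_ms), tolerance = 1e-12)
  }

  # large-series oracle agreement at tight relative tolerance
  set.seed(8)
  rr <- runif(10000, 0.75, 0.88)
  m <- hrv_time(clean_rr(tibble::tibble(rr = rr)))
  expect_equal(m$rmssd, rmssd_brute(rr * 1000), tolerance = 1e-9)
  expect_equal(m$sdnn, sdnn_brute(rr * 1000), tolerance = 1e-9)
})

test_that("time-domain metrics are scale-equivariant", {
  set.seed(9)
  rr <- runif(300, 0.7, 0.9)
  base <- hrv_time(clean_rr(tibble::tibble(rr = rr)))
  scaled <- hrv_time(clean_rr(tibble::tibble(rr = rr * 1.1)))
  expect_equal(scaled$sdnn, base$sdnn * 1.1, tolerance = 1e-9)
  expect_equal(scaled$rmssd, base$rmssd * 1.1, tolerance = 1e-9)
})

test_that("band-limited RR modulation drives the HF fraction", {
  p_hf <- rr_params(mean_rr = 0.8, sd_total = 0.04, lf_frac = 0,
                    hf_frac = 1, resp_rate = 15, seed = 2)
  b <- simulate_rr(p_hf, 300)
  m <- hrv_frequency(clean_rr(b))
  expect_gte(m$hf_power_norm, 0.8)

  p_lf <- rr_params(mean_rr = 0.8, sd_total = 0.04, lf_frac = 1,
                    hf_frac = 0, seed = 2)
  b2 <- simulate_rr(p_lf, 300)
  m2 <- hrv_frequency(clean_rr(b2))
  expect_lte(m2$hf_power_norm, 0.2)

  short <- clean_rr(simulate_rr(rr_params(seed = 1), 60))
  expect_true(is.na(hrv_frequency(short)$total_power))
})

test_that("white-noise RR yields a flat-spectrum HF fraction", {
  set.seed(10)
  fracs <- replicate(100, {
    rr <- 0.8 + rnorm(400, 0, 0.03)
    b <- tibble::tibble(t = cumsum(rr), rr = rr)
    hrv_frequency(clean_rr(b))$hf_power_norm
  })
  span <- 400 * 0.8
  expected <- (0.4 - 0.15) / (0.4 - 1 / span)
  expect_lt(abs(mean(fracs) - expected), 0.05)
})

test_that("Poincare indices follow their closed forms", {
  alt <- clean_rr(tibble::tibble(rr = rep(c(0.825, 0.775), 30)))
  m <- hrv_poincare(alt)
  expect_equal(m$sd1, 25 * sqrt(2), tolerance = 0.5)
  expect_lt(m$sd2, 5)
  expect_lt(m$csi, 0.2)

  set.seed(11)
  iid <- clean_rr(tibble::tibble(rr = 0.8 + rnorm(5000, 0, 0.02)))
  mi <- hrv_poincare(iid)
  expect_lt(abs(mi$csi - 1), 0.1)

  const <- clean_rr(tibble::tibble(rr = rep(0.8, 50)))
  mc <- hrv_poincare(const)
  expect_true(is.na(mc$csi))
  expect_true(is.na(mc$cvi))
})

test_that("QTc follows Bazett and the prolonged-QT count", {
  d1 <- tibble::tibble(qt_ms = 400, rr = 1.0)
  expect_equal(qt_metrics(d1)$qtc_mean, 400)

  d2 <- tibble::tibble(qt_ms = 400, rr = 0.64)
  m2 <- qt_metrics(d2)
  expect_equal(m2$qtc_mean, 500)
  expect_equal(m2$prolonged_qt_frac, 100)  # boundary >= 500 counts

  qtc <- c(480, 500, 510, 490)
  d3 <- tibble::tibble(qt_ms = qtc, rr = 1.0)
  expect_equal(qt_metrics(d3)$prolonged_qt_frac, 50)
  expect_equal(qt_metrics(d3)$prolonged_qt_frac,
               prolonged_frac_brute(qtc))

  # quality and cleaning gates
  d4 <- tibble::tibble(qt_ms = c(400, 400), rr = c(1, 1),
                       quality = c("ok", "no_t"),
                       status = c("kept", "kept"))
  expect_equal(qt_metrics(d4)$n_beats, 1L)
  d5 <- tibble::tibble(qt_ms = numeric(0), rr = numeric(0))
  expect_true(is.na(qt_metrics(d5)$qtc_mean))
})

test_that("measured QTc is invariant when the generator holds true QTc fixed", {
  # build beats with QT = 400 * sqrt(RR) ms: true Bazett QTc = 400 ms
  set.seed(12)
  rr <- runif(500, 0.5, 1.2)   # heart rates 50-120 bpm
  beats <- tibble::tibble(t = cumsum(rr), rr = rr,
                          qt_ms = 400 * sqrt(rr))
  m <- qt_metrics(clean_rr(beats))
  qtc <- beats$qt_ms / sqrt(beats$rr)
  expect_lt(sd(qtc), 1e-9)
  expect_equal(m$qtc_mean, 400, tolerance = 1e-9)
})
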