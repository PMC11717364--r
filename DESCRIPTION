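Package: hrvstim
Title: Treatment-Locked ECG and Heart Rate Variability Analysis for
    Neurostimulation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous ICU electrocardiography around
    repeated neurostimulation sessions, such as transcutaneous auricular
    vagus nerve stimulation (taVNS) delivered to patients with subarachnoid
    hemorrhage. Provides a synthetic cohort generator with per-beat ground
    truth, wavelet-based ECG delineation (R peaks, QRS onset/offset, T
    offset), normal-to-normal interval cleaning, time-domain,
    frequency-domain and Poincare heart-rate-variability metrics, Bazett
    QT correction and prolonged-QT scoring, treatment-locked sliding-window
    metrics with daily-reference z-normalization, exploratory factor
    analysis of autonomic indices (minimum-residual extraction with varimax
    rotation), and the trial statistics battery: normality-gated group
    comparisons, Wilcoxon tests, Bonferroni correction, TOST equivalence
    tests, noncentral-t power analysis, and a random-intercept
    treatment-by-outcome interaction model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
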