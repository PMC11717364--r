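---
title: "Methods: treatment-locked ECG and HRV analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: treatment-locked ECG and HRV analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrvstim)
```

## The problem

Transcutaneous auricular vagus nerve stimulation (taVNS) is being trialled
as a neuromodulation therapy in intensive-care patients with aneurysmal
subarachnoid hemorrhage (SAH). Because vagal stimulation acts directly on
cardiac pacing and repolarization, the safety questions are concrete:
does repeated stimulation cause bradycardia, QT prolongation, or blood
pressure changes, acutely (minutes around a session) or cumulatively
(across days of treatment)? `hrvstim` implements the full analysis chain
needed to answer these questions from continuous bedside monitoring —
500 Hz ECG plus 1 Hz vitals — around a twice-daily schedule of 20-minute
stimulation sessions, together with a synthetic cohort generator rich
enough to give every stage of the chain a known ground truth.

## Pipeline overview

1. **Synthesis** (`rr_params()`, `simulate_rr()`, `simulate_ecg()`,
   `simulate_event_channel()`, `simulate_vitals()`, `cohort_spec()`,
   `simulate_cohort()`): synthetic subject-days with per-beat truth.
2. **Delineation** (`ecg_preprocess()`, `detect_r_peaks()`,
   `delineate_waves()`): filters, R-peak detection from the gradient
   envelope, and wavelet delineation of QRS onset/offset and T offset.
3. **Metrics** (`clean_rr()`, `hrv_time()`, `hrv_frequency()`,
   `hrv_poincare()`, `qt_metrics()`, `cardiac_metrics()`):
   normal-to-normal interval cleaning and the cardiac metric set.
4. **Windows** (`detect_sessions()`, `windowed_metrics()`,
   `normalize_daily()`, `session_contrasts()`, `daily_summaries()`):
   treatment-locked sliding windows, daily-z normalization, acute
   contrasts, and daily change-from-Day-1 summaries in 3-day bins.
5. **Factors** (`bartlett_sphericity()`, `fit_hrv_factors()`,
   `score_factors()`): a two-factor model of seven autonomic indices.
6. **Statistics** (`compare_groups()`, `signed_rank_vs_zero()`,
   `tost_equivalence()`, `achieved_power()`, `required_n_per_group()`,
   `pearson_with_test()`, `fit_outcome_model()`, `ancova_age()`).
7. **Orchestration** (`pipeline_config()`, `run_pipeline()`,
   `pipeline_report()`): a reproducible end-to-end run with plain-text
   artifacts. The package's interface is its functions; `run_pipeline()`
   is the single entry point a script would call.

## The synthetic cohort generator

The generator is first-class, tested code: its outputs define the
conditions under which the pipeline's guarantees are demonstrated.

**RR process.** Beat-to-beat intervals are a mean plus two sinusoids —
0.1 Hz (the Mayer-wave/low-frequency band) and the respiratory frequency
`resp_rate/60` Hz — with randomized phases and a white Gaussian
remainder. Amplitudes are chosen so `lf_frac` and `hf_frac` of the total
variance (`sd_total`², the target SDNN) sit in those bands, which makes
spectral band fractions directly assertable. This is deliberately the
simplest process with controllable band powers, not an
integral-pulse-frequency model of the sinoatrial node.

**Ectopic beats.** With probability `ectopic_rate` a beat is made
premature by shortening its interval 25–40% relative to the previous
emitted interval, so every injected ectopic violates the >20%
relative-difference exclusion rule by construction — the cleaning stage
has an exact oracle. Single premature beats are the only arrhythmia
modelled.

**ECG morphology.** Each beat is a sum of five Gaussians (P, Q, R, S, T)
in lead-II proportions, in the spirit of ECGSYN. The per-beat QT is
`qt_base + qt_rr_slope·(RR − 1 s)`; the T-wave Gaussian is placed so the
true T offset falls exactly at QRS onset + QT, and P/T widths and the
P offset compress with √RR as cycle length shortens, as real atrial and
repolarization geometry does. Ground-truth fiducials are defined
geometrically (QRS bounds at 2.5 SD outside the Q/S Gaussians; T offset
2.33 SD past the T peak, the point where a Gaussian-derivative limb
decays to 25% of its extremum — the same criterion the delineator uses).

**Cohort.** Defaults mirror the trial shape: 11 active / 13 sham
subjects, ~11 monitored days each, two 20-minute sessions per day at
least 60 minutes apart (the inter-session spacing is a free parameter of
the design; 60 minutes keeps pre/post periods of adjacent sessions from
overlapping). Group-level daily drifts (heart rate, QTc, SDNN, vitals),
an acute post-session heart-rate jump, and a linkage between that jump
and the subject's mRS change (`mrs_slope`, default −1.85 bpm per mRS
point in the active arm) are all injectable; defaults otherwise produce
a null cohort. `day_seconds` defaults to 86400 (continuous 24-hour
monitoring); tests and the acceptance script compress the day (2–6 h)
to keep runs desk-sized — the session geometry, not the day length,
drives the analysis.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: true SAH hemodynamics (vasospasm,
medication effects, ICP waves), nonstationary HRV, morphology variants
(bundle branch block, atrial fibrillation, U waves), electrode artifacts
beyond white noise and 60 Hz interference, and missingness other than
clean masked gaps. Results on real recordings depend on the delineator
coping with morphology the generator never produces.

## Delineation

Preprocessing follows the clinical pipeline exactly: a fifth-order
0.5 Hz high-pass Butterworth filter and a 60 Hz notch, both run
forward–backward so fiducials are not displaced by filter delay (the
phase convention is our choice; zero-phase keeps QT unbiased). Gap masks
are dilated by 1 s per side because ringing bleeds into gap
neighbourhoods. A second pass of the preprocessing changes the interior
of the signal by less than ~1% — bounded by the filter's passband
deviation at the beat fundamental (≈1e−4 per pass at 75 bpm), not by
arithmetic precision; exact idempotence would require an ideal filter.

R peaks come from the steepness of the absolute gradient: the signal is
confined to the QRS energy band (≤25 Hz), the rectified first difference
is smoothed into a 120 ms envelope, candidates are envelope maxima above
35% of the local (2 s) envelope ceiling with a 250 ms refractory period,
and the R peak is refined as the extremum of |ECG| nearby — which makes
the count polarity-invariant.

Wave boundaries use an à-trous dyadic wavelet transform with the
quadratic-spline filter pair (lowpass ⅛·[1,3,3,1], highpass 2·[1,−1])
over scales 2¹–2⁵, time-aligned by the filters' group delays. QRS onset
is found from the modulus-maxima pair flanking the R peak: the nearest
preceding maximum within 50 ms (the Q limb; anything farther is the P
wave) is walked backwards until the modulus falls below
`qrs_bound_frac` (default 0.3) of it. The T wave is sought at scale 2⁴
in a window from `min(80, 120·RR) ms` after QRS offset to
`max(400, 600·RR) ms`, clipped 160 ms clear of the next R peak; its
offset is where the smoothed modulus stays below `t_off_frac` (default
0.25) of the descending-limb maximum for 20 ms. The opposite-sign
partner of a modulus maximum must lie within 150 ms, otherwise the
response is treated as monophasic — this stops the T search from pairing
with the next beat's P wave at high heart rates. Waves that cannot be
resolved are flagged (`no_t`, `no_p`, `edge`), never interpolated.
Threshold defaults were fixed once against the generator's geometric
truth on a 40–140 bpm, 10–20 dB SNR sweep; on that sweep R-peak F1
exceeds 0.99 and the median QT error is below 10 ms. QT is measured from
QRS onset (the delineator family's convention; the clinical text leaves
the start fiducial implicit).

## Metrics

`clean_rr()` applies the exclusion rules in order: intervals over 2 s or
under 300 ms are out of range; then intervals differing by more than 20%
(strictly) from the previous **kept** interval are ectopic. Comparing to
the previous kept rather than previous raw interval prevents one outlier
from cascading exclusions — the rule's reference is ambiguous in prose,
and this reading is the conservative one. The exclusion ledger is
complete: kept + too_long + too_short + ectopic equals the raw count.

Time-domain metrics are the standard Task-Force definitions (RMSSD over
successive kept pairs that were adjacent in the raw series; SDNN with
the N−1 denominator; pNNI-50 strictly >50 ms per its name), pinned by
brute-force loop oracles in the tests. Spectral metrics resample the
kept-interval tachogram at 4 Hz by cubic spline and integrate the
periodogram: total power over (1/span, 0.4] Hz and the 0.15–0.4 Hz
fraction of it; the lower bound of "power below 0.4 Hz" is unstated in
the source analysis, so 1/window-span is used and stated here. Poincaré
indices use Toichi's formulation (CSI = SD2/SD1,
CVI = log₁₀(SD1·SD2·16)), with SD1/SD2 from the variance identities on
successive differences. QTc is Bazett's QT/√RR; prolonged
repolarization is the percentage of eligible beats (delineation `ok`,
preceding interval kept) with QTc ≥ 500 ms. Both mean and median daily
QTc are emitted; the mean is the headline aggregate.

## Treatment-locked windows

Sessions are recovered from the event channel by rectification, a 1 s
moving mean, and binarization at half the channel's robust (99.9th
percentile) maximum; pulses shorter than 5 minutes are logged and
dropped. Metrics are computed in 6-minute windows stepped 3 minutes,
tiling the 20 minutes before onset, the stimulation period, and the
20 minutes after offset; the same geometry tiled over the whole day
provides each subject-day's reference mean and SD for z-normalization
(at least 20 reference windows required; zero-SD metrics yield NA).
Reference windows include the treatment periods, matching the stated
procedure of tiling "each day"; with two 20-minute sessions in a 24-hour
day the contamination this causes in the reference statistics is ~3%,
and the half-SD bump-recovery test uses a 6-hour day for the same
reason. Windows with less than 80% beat coverage (gaps) are dropped.
Contrasts are period means: during−pre and post−pre, in raw and daily-z
units. Daily summaries aggregate over the civil day anchored at the
recording start, subtract each subject's Day 1 value, and bin days 2–4,
5–7, 8–10, 11–13; each subject-day is treated as an independent sample
downstream, mirroring the trial's own justification (large day-to-day
variation in ICU physiology).

## Factor analysis

The input is one row per sliding window, with the seven indices (RMSSD,
SDNN, pNNI-50, total power, normalized HF power, CVI, CSI) in their
daily-z form — standardized by the subject-day's own reference mean/SD,
so between-subject and between-day level differences are removed before
pooling. (The alternative reading — one row per subject-day z-scored by
its own day — is degenerate: a daily aggregate standardized against its
own day's windows is near zero by construction.) Bartlett's sphericity
test gates the analysis with a warning, not an abort. Extraction is
minimum-residual (ULS), implemented in-package: uniquenesses are
optimized by L-BFGS-B to minimize the squared off-diagonal residuals of
R − ΛΛ′, with loadings from the eigen-decomposition of the reduced
matrix and squared-multiple-correlation starts. Varimax rotation
(Kaiser-normalized, eps 1e−10 so re-rotation is a no-op to 1e−5) and a
sign convention (each factor's loading sum positive) follow. Factors are
labelled by pattern: the larger positive loading mass on
{RMSSD, SDNN, pNNI-50, total power} names *overall HRV*; the other
factor must load positively on RMSSD and HF power and negatively on CSI
to be named *parasympathetic activity*, else labels stay NA with a
diagnostic. Scores are regression (Thurstone) scores — the scoring
estimator is not specified in the source analysis, and regression
scores are the common default. The number of factors is a configuration
(default 2, the scree choice); eigenvalues of the correlation matrix are
reported for scree inspection but no automatic selection is applied.

## Statistics

Group comparisons are gated by Shapiro–Wilk on both groups (α = 0.05,
unstated in the source and fixed here): both normal → pooled-variance
two-sample t-test, otherwise Mann–Whitney U; constant samples fall back
to Mann–Whitney with a message. P-values are Bonferroni-multiplied by
the family size — 6 for the cardiac battery (HR, QTc, RMSSD, SDNN, and
the two factors; this factor is explicit in the source) and 4 by
default for the vascular battery (BP, PPI, respiration rate, ICP; the
source says only "Bonferroni corrected", so the factor is configuration,
logged in every result row). Cohen's d (pooled, n−1 weights) is always
attached, and whenever a result is non-significant the achieved power of
a d = 0.5 pooled t-test at the observed group sizes is reported.
Equivalence is standard TOST with pooled-variance one-sided t-tests at
the pre-specified margins (5 bpm heart rate, 50 ms QT, 2 mmHg blood
pressure); the source's phrase "two-tailed equivalence tests" is read as
TOST, whose two one-sided tests are the standard operationalization.
Power analytics use the exact noncentral-t distribution of the pooled
two-sample t-test; `achieved_power(94, 95)` = 0.93 (2 dp) and
`required_n_per_group(0.80)` = 64 reproduce the trial's printed values,
and the two functions are mutually inverse by construction. The
pooled-variance (not Welch) t-test is the default throughout because it
is the test those classic power formulas describe; Welch is available by
flag.

The acute-outcome model is
`hr_change ~ group * mrs_change + (1 | subject)`, REML, fitted with
lmerTest for denominator-df p-values and Wald confidence intervals (fast
and accurate at these sizes; profile CIs are available). The response is
the per-session post−pre heart-rate change in daily-z units — the
normalized scale is the default because the acute analyses are reported
on normalized heart rate; the raw-bpm response is a flag away. Degenerate
designs (a term dropped for rank deficiency) keep the four-term
coefficient layout with NAs rather than erroring. The age-adjusted
comparison is an ordinary ANCOVA `change ~ group + age_decade`, dropping
the age term with a message when age is constant.

## Problem sizes and numerical tolerances

The test suite and acceptance script run at sizes chosen to exercise
every guarantee in minutes on one CPU: delineation sweeps use 60 s
records at six heart rates × two SNRs; oracle equivalence uses 1000
random series; bump recovery uses 50 six-hour days; factor recovery and
mixed-model coverage use 100 replicate cohorts (300 observations and
24 subjects respectively); familywise error uses 500 null cohorts of 20
subjects × 3 days at the metric level (the battery consumes per-day
changes, so metric-level nulls exercise exactly the code under test).
Time-domain oracles agree to 1e−9; normalization self-consistency to
1e−9; band fractions to ±0.05; QT recovery to 10 ms median; coverage
and labeling rates to their stated counts.

## Known limitations

QTc dispersion, nonlinear HRV (entropy, DFA), respiration-gated
corrections, multi-lead fusion and arrhythmia classification are out of
scope. The delineator is calibrated on synthetic morphology; real-world
T-wave morphologies (biphasic, flat, U-wave fusion) will lower the `ok`
fraction and should be monitored via the quality flags. The mixed model
treats sessions as exchangeable within subject (no day-level
autocorrelation), and daily comparisons treat subject-days as
independent — both inherited, deliberately, from the trial's own
analysis framework.
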