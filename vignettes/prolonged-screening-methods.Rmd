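---
title: "Methods: prolonged T:R screening from Holter ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prolonged T:R screening from Holter ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SICDscreen)
```

# The screening problem

The subcutaneous ICD discriminates rhythm on a far-field signal; if the
T wave is large relative to the R wave, the device can double-count and
deliver inappropriate therapy. Pre-implant screening therefore asks whether
the T:R amplitude ratio on each of three sensing vectors stays below a
threshold. A single resting electrogram snapshot cannot see circadian,
autonomic or postural excursions of the ratio; screening over a full
24-hour Holter recording can. The unit of analysis is the 10-second
segment: 8640 per channel per day at 500 Hz.

Decision rules implemented here:

* favourability is *strict*: a segment is favourable at threshold $t$ iff
  its ratio is $< t$, for $t \in \{1/3, 1/2, 2/3, 3/4, 1\}$;
* a vector **fails** a threshold if it is unfavourable for 20 consecutive
  seconds, i.e. two successive 10-second segments;
* a patient **passes** a threshold if at least one non-missing vector
  passes;
* the *standard pass probability* is the fraction of segments with at least
  one favourable vector at 1:3 — the probability that a conventional
  one-shot screen, landing at a random moment of the day, would pass the
  patient.

Missing per-segment estimates (too few beats, no rhythm, low signal-to-noise)
never count as favourable and break unfavourable runs conservatively: a run
is only scored across contiguous non-missing unfavourable segments.

# Synthetic generator

No public per-segment-labeled Holter corpus exists at this scale, so the
package ships a generator whose ground truth is known exactly.

Each beat is a sum of five Gaussians (P, Q, R, S, T) on the cycle-phase
axis. The T amplitude is `trRatio` × the R amplitude, so the target ratio
is a direct model parameter; per-segment targets follow a trajectory with a
baseline, a circadian sinusoid and white jitter, truncated to be
non-negative. The ground-truth series is *realised from the noise-free
waveform construction*, before baseline wander (0.2–0.5 Hz sinusoids),
50 Hz interference and white noise are added — estimators are therefore
judged against the truth the noise corrupted, not against another estimate.

```{r}
out <- generateRecording(simConfig(duration = 30, seed = 1))
trValues(out$truth$primary)
```

Subgroup presets (`generateCohort()`) differ in baseline ratio, circadian
amplitude and jitter — e.g. the "Normal" preset sits near 0.20 with small
excursions while the "S-ICD" preset sits near 0.55 — so simulated cohorts
produce subgroup-separated outcomes without any estimator in the loop.

**Realism limits.** Beats are strictly periodic within a recording (no
heart-rate variability or rhythm change), morphology is fixed per channel,
noise is stationary, and electrode artefacts (dropout, motion spikes,
saturation) are absent. The generator supports method validation — it is
not a substitute for clinical recordings, and numbers obtained on it should
be read as *scaled-down procedural* results, not clinical performance.

# Conditioning chain

`preprocessSegment()` applies three steps, each chosen so its contract can
be tested exactly.

**Baseline removal** projects the segment onto a low-frequency cosine basis
$\cos(\pi k (i - 1/2)/n)$, $k = 0 \dots K$, and subtracts the projection.
$K$ is set from a 0.5 Hz cutoff plus a 0.3 Hz transition allowance
($K = 16$ for 10 s). Because this is an orthogonal projection it is
*exactly* idempotent and maps constants to zero — properties a forward–
backward IIR high-pass only approximates — while attenuating the 0.2–0.45 Hz
wander band strongly and leaving cardiac frequencies essentially untouched.

**Powerline cancellation** fits the best least-squares sinusoid at the mains
frequency (sine and cosine regressors) and subtracts it. On a 10-second
window the mains frequency is resolved exactly, so on-frequency rejection is
near machine precision, and the operation is again an idempotent projection.
A conventional notch IIR would attenuate a neighbourhood of 50 Hz; the
regression instead removes only the two degrees of freedom the interference
occupies.

**Low-pass** is a zero-phase order-4 Butterworth at 40 Hz, applied
forward–backward with mirror-reflection padding to suppress edge
transients. Zero phase matters: the R peak must not move, or downstream
peak-pairing and the PSR image geometry would be biased.

```{r}
tg <- (0:4999) / 500
tone <- new("ECGSegment", samples = sin(2 * pi * 50 * tg), samplingRate = 500,
            channelRole = "primary", segmentIndex = 0L, startTime = 0)
sd(notchPowerline(tone)@samples) / sd(tone@samples)  # residual 50 Hz fraction
```

The chain as a whole is not exactly idempotent (the IIR low-pass is not a
projection), but the tests bound the second-pass change below 1% RMS on
realistic beat trains.

# PSR imaging

Each conditioned segment is mapped to a 32×32 delay-embedding occupancy
image: amplitudes are min–max normalised to $[0,1]$ and the pairs
$(x(t), x(t+\tau))$ are binned, $\tau = 10$ samples (20 ms at 500 Hz). The
image has exactly $N - \tau$ counts, is invariant to amplitude scaling, and
transposes under time reversal — three properties the test suite checks
against a brute-force binning oracle.

The 20 ms delay is short relative to QRS width, so the trajectory leaves the
diagonal during fast deflections and hugs it during slow ones; R and T wave
excursions occupy distinct regions whose *position along the normalised
amplitude axis* encodes the T:R ratio. A constant segment cannot be
normalised; it maps, with a warning, to a single centre pixel.

# T:R estimators

**Waveform estimator** (`oracleTR()`, `backend = "oracle"`). R peaks are
found on a smoothed squared-derivative envelope with a refractory merge;
the T peak is the extremum in a physiological window after each R (120 ms
to 60% of the RR interval), measured against a per-beat local isoelectric
level. The per-segment ratio is the median over beats. Segments with fewer
than three beats, no detectable rhythm, or amplitude below a noise gate
return `NA` with a reason code.

**Image regressor** (`trainRegressor()`, `predictTR()`). A ridge regression
on fixed image features: 3×3 convolution summaries (smoothing, horizontal /
vertical / diagonal edges, average-pooled), row and column marginals, and —
the feature family that matters most — interpolated quantiles of the
amplitude marginal, dense in the upper tail, plus their ratios to the top
quantile. The rationale: the T cluster contributes a large occupancy mass
at normalised amplitude ≈ T:R (the T wave is slow, so the trajectory dwells
there), while the R excursion is fast and contributes little mass at the
top. Upper-tail quantiles of the amplitude marginal therefore track the
T:R ratio almost linearly, which a linear readout of raw pixels cannot do.
The ridge penalty is chosen by generalised cross-validation on the training
fold only.

Evaluation is tenfold cross-validation with folds assigned *by recording*,
never by segment — segments of one recording share a trajectory and noise
realisation, so segment-level folds would leak. Pooled out-of-fold MAE and
RMSE are reported; `scripts/acceptance.R` runs the full 2000-segment
experiment from a single seed.

# Cohort statistics

Fail/pass × subgroup tables are tested with a two-sided exact Fisher test
computed by complete recursive enumeration of all tables with the observed
margins, in log-factorial arithmetic. The two-sided definition sums the
probabilities of tables no more probable than the observed one (with a
$10^{-7}$ relative guard against floating-point ties). The enumeration also
returns the total probability mass as a self-check; tests require it to be
1 within $10^{-9}$ and verify 2×2 agreement with the closed-form
hypergeometric sum and with `stats::fisher.test`. Continuous summaries
(standard pass probabilities across subgroups) use Kruskal–Wallis with tie
correction and the $\chi^2$ approximation.

```{r}
fisherExactRxC(cohortTable(fail = c(4, 3, 7, 0, 3), pass = c(2, 4, 7, 7, 0),
                           subgroups = c("ACHD", "HCM", "HF", "Normal", "S-ICD")))
```

# Design rationale and limitations

* S4 classes with validity checks (recordings, segments, images, series,
  screening results, test results) catch unit and shape errors at
  construction time rather than deep inside pipelines.
* The subgroup presets and generator defaults are free modelling parameters,
  fixed before any evaluation; accuracy results are specific to them.
* The regressor is a linear model on engineered features, not a deep
  network: at 32×32 resolution and with position-encoding features the
  extra capacity is unnecessary, and the model trains in seconds on one CPU
  while remaining exactly reproducible.
* The 20-second rule, the strict inequality, and the five thresholds are
  fixed protocol constants of the screening rule, not tunables.
* Known limitations: no heart-rate variability, arrhythmia, or non-
  stationary noise in the generator; the waveform estimator assumes a
  dominant R and a single T per cycle; Fisher enumeration cost grows
  rapidly with margins beyond the 2×5 / n≈40 scale used here (a budget
  guard stops runaway tables).
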