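---
title: "Beat-by-beat PAT/PTT extraction and calibrated blood pressure estimation"
author: "patbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-by-beat PAT/PTT extraction and calibrated blood pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patbp)
```

## The problem and the model

Continuous, cuffless blood pressure (BP) monitoring from wearable signals
usually leans on the timing of the arterial pulse. Two delays are in play:

* **Pulse arrival time (PAT)** — from the ECG R-peak to a pulse landmark at
  a distal site. PAT contains the pre-ejection period (PEP, the
  electromechanical delay before the aortic valve opens) plus the arterial
  transit time.
* **Pulse transit time (PTT)** — between two arterial sites; here, from the
  foot of the invasively measured radial arterial pressure (ABP) to a
  landmark of the finger photoplethysmogram (PPG).

Arterial compliance falls as pressure rises, so both delays are expected to
shorten with rising BP: the working model is a per-subject *inverse linear*
relation between PAT and BP. `patbp` implements the full chain needed to
test and exploit that relation beat by beat on time-synchronized ECG, PPG
and ABP records sampled at 100 Hz:

1. **Preprocessing.** Cascaded-median baseline removal for ECG and PPG;
   Pan-Tompkins R-peak detection; recording-level gating (duration, mean
   heart rate, saturation screen); moving 10-beat ensemble averaging of the
   ABP and PPG cycles between consecutive R-peaks.
2. **Fiducials.** Per averaged cycle: ABP foot (valley) and peak; PPG
   diastolic minimum, systolic peak, maximum-upslope point and the
   **intersecting-tangent (IT)** onset — the intersection of the tangent at
   the maximum upslope with the horizontal tangent through the diastolic
   minimum,
   $t_{IT} = t_{md} - \bigl(y(t_{md}) - y_{min}\bigr) / y'(t_{md})$.
3. **Features.** Per cycle: SBP (ABP peak value), DBP (ABP foot value), MBP
   (cycle mean), PP = SBP − DBP; PAT\_ABP (R-peak to ABP foot) and four
   PAT\_PPG / PTT pairs indexed by the PPG landmark (1 valley, 2 peak,
   3 maximum derivative, 4 IT), with the identity
   PTT\_k = PAT\_PPG\_k − PAT\_ABP. Six plausibility conditions gate each
   beat; surviving series are smoothed with a 20 s window; subjects with
   fewer than 100 valid beats are excluded.
4. **Modelling.** Per-subject Pearson correlations between the four BP
   values and the nine temporal features; a pooled linear model
   $BP = \alpha_1 \cdot PAT_{PPG4} + \alpha_0$ calibrated per subject by
   mean-centering both variables before the pooled fit and adding the
   subject's mean BP back as $\alpha_0$; multivariate regression of
   per-subject slopes/correlations on risk factors (age, gender, BMI,
   hypertension, diabetes) with standard errors, t p-values and VIFs.
5. **Evaluation.** Pooled ME/SDE/MAD, cumulative error percentages within
   5/10/15 mmHg, and grading against AAMI (|ME| ≤ 5, SDE ≤ 8 mmHg), BHS
   (A ≥ 60/85/95, B ≥ 50/75/90, C ≥ 40/65/85, else D) and IEEE 1708
   (MAD ≤ 5/6/7 mmHg for A/B/C). The standards' thresholds live in
   configuration because they come from the standards documents, not from
   this package.

A structural consequence of the mean calibration is worth stating: the
centered pooled fit has zero intercept by construction, so the per-subject
(and pooled) mean prediction error is *exactly* zero up to floating-point
rounding. The package keeps that property exact by constraining the
centered intercept rather than estimating it.

## The synthetic-data generator

There is no public clinical data in this package; every stage is tested
against a seeded waveform simulator with analytic per-beat ground truth.

**What it emulates.** A beat train (40–200 BPM supported, default 75 BPM)
with R-peaks snapped to the 100 Hz grid; SBP/DBP trajectories made of a
slow sinusoid (default period 10 min), a bounded per-beat random walk and
optional user trajectories; a PAT coupling law
`pat_abp = pep_ms + intercept + slope · SBP` with non-positive slope plus
per-beat noise; a peripheral (PTT) leg that is by default *decoupled* from
BP — this deliberate contrast (strong PAT coupling, weak PTT coupling) is
what the correlation-analysis tests exercise; an optional constant
**device delay** applied to the PPG channel only, emulating a fixed
acquisition offset between the pulse-oximetry channel and the ECG/ABP
channels; baseline wander, additive white noise, and clamping/dropout
artifacts.

**Waveform templates.** Each ABP/PPG pulse is a two-Gaussian bump
(systolic wave + dicrotic wave) on normalized phase, chord-corrected so
the cycle starts and ends at exactly zero and the diastolic foot is a
V-shaped minimum. The template's landmark phases (peak, maximum upslope,
IT onset) are computed once to ~1e-10 phase precision, so a pulse warped
onto a beat of duration $T$ has analytically known fiducial times — the
ground truth the extraction pipeline is scored against. ABP cycles are
scaled so the per-cycle maximum and minimum equal the beat's true SBP and
DBP; ECG beats are a narrow Gaussian QRS plus a low T wave.

**Ground-truth conventions.** Ground truth stores *physiological*
(delay-free) PAT/PTT values, and PTT\_k = PAT\_PPG\_k − PAT\_ABP holds
exactly for every beat. Adding a device delay therefore leaves the ground
truth bit-identical, shifts every *measured* PAT\_PPG by exactly the
delay, and — because the measured PTT is defined through the same identity
— shifts the measured PTT by the same constant while the physiological PTT
is unchanged. A constant offset cancels from within-subject correlations
and from the mean-calibrated model, so it does not affect the analyses.

**Default cohort sampler.** Per subject: age 58 ± 15 y (clipped 20–92),
53% male, BMI 23 ± 4, 34% hypertensive, 11% diabetic; mean SBP 116 ± 15
mmHg (clipped 95–160), SBP–DBP gap 53 ± 8 mmHg (floored so DBP stays above
50 mmHg at baseline), oscillation amplitude 16 ± 8 mmHg (clipped 3–25),
heart rate 75 ± 10 BPM (clipped 50–110), record length 30 min. The clip
bounds are part of the study-condition design: they keep the *sampled*
physiology inside the pipeline's own plausibility bands (PAT\_ABP within
70–250 ms, DBP above 30 mmHg), so that beats are lost to noise and
artifacts, not to a generator that contradicts its own pipeline. With the
default coupling (slope −1 ms/mmHg, PAT\_ABP = 150 ms at SBP 120, a
peripheral delay of 150 ms) the simulated PAT\_ABP ≈ 150 ms and
PAT\_PPG\_4 ≈ 300 ms sit at textbook values.

**What it does not emulate.** No respiration or cardiac-output modulation,
no arrhythmia, no reflected-wave morphology changes with vasomotor tone,
no PEP variability (PEP is a constant 60 ms by default — the true PEP
distribution in surgical cohorts is not something this package can claim).
Passing tests therefore demonstrate correctness of the *pipeline
mechanics* (detection, gating, calibration algebra, grading) under
controlled conditions, not clinical performance on real data.

## Numerical and design choices

* **Baseline removal** is a cascade of two running medians subtracted from
  the signal. ECG uses 250/600 ms windows (shorter than any inter-beat
  structure, longer than the QRS). PPG uses 1000/1500 ms windows: a median
  window shorter than one cardiac cycle tracks the pulse morphology itself
  and visibly biases the diastolic-minimum and IT fiducials, while windows
  at or above one cycle are nearly phase-invariant for periodic pulses.
  ABP is never baseline-filtered — its absolute mmHg calibration *is* the
  measurement.
* **Pan-Tompkins** runs zero-phase (filtfilt band-pass 5–15 Hz, symmetric
  five-point derivative, squaring, 150 ms integration) with the classic
  adaptive dual thresholds and a 200 ms refractory period; R times are
  refined to the band-passed maximum near each accepted integration peak.
  Zero-phase filtering makes detection exactly translation-equivariant,
  which the tests assert to machine precision.
* **Ensemble averaging** aligns the cycles of 10 consecutive beats at
  their R-peaks and truncates to the window's shortest RR rather than
  time-warping: warping would resample the time axis and destroy the
  sample-accurate fiducial timing the features need. The averaged cycle is
  attributed to the window's first beat. A consequence: every fiducial of
  a beat must occur within one RR of its R-peak, so very large PPG device
  delays are only analyzable at correspondingly slow heart rates; the
  delay tests run at 48 BPM for this reason.
* **ABP foot** = deepest local minimum inside the 50–400 ms gating window
  (ties to the earliest). Requiring a local minimum rejects monotone
  cycles; taking the deepest rather than the first avoids latching onto
  shallow noise dimples on the diastolic tail, which would bias PAT\_ABP
  early by an amount that co-varies with pulse pressure.
* **IT onset** is kept as a real (sub-sample) time: at 100 Hz the 10 ms
  grid is the dominant error source, and the tangent intersection is
  well-defined between samples. It is clamped to
  [valley, maximum-derivative] to guard against degenerate tangents.
* **Fiducial gating ranges** (ABP valley 50–400 ms; PPG points 50–1500 ms
  after the R-peak) are configuration, deliberately wide on the PPG side
  to admit device-delayed channels; the source cohorts for such pipelines
  never publish their exact ranges, so these are package defaults, not
  reconstructions.
* **Plausibility conditions** are evaluated in numbered order and the
  first failure is recorded. The 5 s look-back uses the nearest
  already-accepted beat at least 5 s earlier (no interpolation) and passes
  vacuously at the start of a record; beats invalidated earlier never
  serve as references and are excluded from smoothing windows entirely.
  The BP-jump condition applies the 30 mmHg bound to SBP and DBP each.
* **Smoothing** is a centered ±10 s moving average over valid beats (a
  trailing window is available by configuration). Smoothing is linear, so
  it commutes with the PTT identity and with per-subject centering.
* **Subject gate**: valid beats are counted after the conditions, then
  smoothed, then the ≥ 100-beat rule is applied; the count is unaffected
  by smoothing, so the order only matters for what the series contains.
* **Model fitting** uses the closed-form zero-intercept OLS slope on the
  pooled mean-centered pairs. Zero pooled variance of the centered
  predictor is an explicit error, as are undefined (zero-variance)
  correlations — degenerate inputs fail loudly rather than silently
  propagating NA.
* **Confounder regression** encodes gender as male = 1, binary
  comorbidities as 0/1, leaves continuous covariates unstandardized (so
  coefficients are per-year, per-kg/m² effects), and reports
  VIF = 1/(1 − R²_j). A rank-deficient design names the aliased columns
  in its error.
* **Evaluation** reports pooled metrics over all beat pairs *and*
  per-recording metrics: pooled numbers are what the monitor standards
  grade, but per-recording correlations reveal subjects whose estimates
  track poorly even when the pooled grade looks good — the central caveat
  of applying cuff-oriented standards to beat-by-beat estimators.

## Problem sizes used by the tests and the acceptance script

The test suite runs entirely on generated data: module tests use records
of 1–7 minutes; the end-to-end calibration check and the acceptance script
use 20 subjects × 30-minute records (≈ 45,000 valid beats pooled), and the
slope-recovery check uses 20 replicates of 50 subjects × ≈ 1000 beats at
the generator's beat-truth layer — the same code path the waveform
renderer consumes, which keeps the check honest while avoiding a
million-beat waveform simulation. These sizes were chosen as the smallest
cohorts at which the checked quantities are stable.

## Known limitations

* Fiducials are searched within one RR interval of the R-peak; extreme
  device delays at fast heart rates push PPG landmarks into the next
  cycle and those beats are rejected rather than recovered.
* The mean-calibration property (ME ≡ 0) is exact only when predictions
  are evaluated on the same beats the calibration means were computed
  from; prospective use requires an explicit calibration phase.
* The saturation screen targets clamped/flat segments; it is not a
  general artifact detector (no motion artifacts, no damped-waveform
  detection).
* `fs` values other than 100 Hz are accepted and propagated, but the
  defaults (filter bands, windows) are tuned for 100 Hz and tested there.
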