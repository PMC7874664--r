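---
title: "Perfusion mapping from dynamic chest radiographs: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion mapping from dynamic chest radiographs: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdr)
```

## The physical signal and the analysis model

A flat-panel detector imaging the chest at ~15 frames/s during a
breath-hold sees two slow modulations of each pixel's value: a residual
respiratory/drift component well below 0.85 Hz, and a cardiac-synchronous
component near the heart rate (0.85–3 Hz covers 51–180 beats/min). Over
the lung fields the cardiac component arises from pulsatile blood volume:
more blood in the beam path means more attenuation, so lung pixel values
*fall* during systole while the ventricle region — where blood is being
ejected into view — moves the opposite way. The analysis exploits exactly
this anti-phase relation:

1. high-pass filter every series at 0.85 Hz to isolate the cardiac band;
2. take the filtered mean of a 25 × 25 mm ventricle ROI as the cardiac
   reference `PC_lv(t)`;
3. for each lung pixel, compute the Pearson correlation between
   `-PC_lv` and the pixel's filtered series over a sliding window, frame
   by frame (`CCv`, in [-1, 1]), and reduce per pixel to the maximum over
   frames (`MaxCCv`);
4. sum `MaxCCv` over each lung field and form the affected side's share,
   the blood flow ratio (BFR);
5. scale the preoperative FEV1/DLco by `BFR_intact +
   remaining/total_affected × BFR_affected` to predict the postoperative
   value; compare with plain segment counting `(19 − resected)/19`.

When the affected side's BFR equals its segment share of 19 (10/19 right,
9/19 left) the perfusion-weighted formula reduces algebraically to segment
counting; the test suite verifies this identity for every lobectomy.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff_hz` | 0.85 | Hz | separates respiratory (<~0.5 Hz) from cardiac (>0.85 Hz) bands |
| filter order / phase | 4th-order Butterworth, forward–backward | — | zero phase preserves the timing the correlation depends on |
| `window_frames` | one estimated cardiac period, odd, ≥5 | frames | shortest window over which phase agreement is meaningful |
| `spatial_bin` | 1 (off) | pixels | correlation is defined per pixel; binning is an optional noise-reduction knob |
| `saturation_frac` | 0.10 | — | pixels saturated in more than 10% of frames carry no usable signal and are flagged undefined |
| `clip_negative` | FALSE | — | negative MaxCCv values (pure-noise pixels) are kept in sums by default, preserving the plain summation definition |
| risk-band edges | 40/70 (FEV1), 40/60 (DLco) | % | standard surgical risk stratification; boundary values belong to the upper band |

The windowed correlation needs a period estimate; it comes from the
dominant peak of the reference spectrum in the 0.85–3 Hz band. Detection
requires the peak periodogram ordinate to exceed 20× the band median at
native frequency resolution — native-resolution bins of a noise spectrum
are approximately independent, so a noise-only band essentially never
reaches that ratio, while any usable cardiac line exceeds it by orders of
magnitude. A failure raises "no cardiac component detected" rather than
returning a spurious period.

## What the synthetic generator emulates — and what it does not

`generate_sequence()` produces, per pixel and frame,

```
baseline − A_perf(x, y) · s_card(t) + A_resp · s_resp(t) + ε    (lung fields)
baseline + A_vent · s_card(t) + ε                               (ventricle ROI)
```

with i.i.d. Gaussian ε, clipping to `[0, saturation]`, and a stored ground
truth (amplitude map, left-lung amplitude fraction, exact component
waveforms). Acquisition defaults mirror a clinical protocol — 15 frames/s,
16-bit values saturating near 58,000, 0.417 mm pixels at the full
1024 × 1024 grid — scaled to 128 × 128 × 150 frames so that a single
sequence simulates and maps in about a second; tests and the acceptance
script use this desk scale throughout, and the full-scale geometry is
available by setting the size parameters. The cardiac waveform is a
sinusoid by default, with an asymmetric fast-upstroke alternative for
robustness checks, because the true ventricular waveform shape is not
specified by the imaging protocol. The residual respiratory amplitude
under breath-hold is likewise a free fixture parameter (default 60
pixel-value units, a small fraction of the perfusion amplitudes).

Deliberately *not* modelled: anatomical thorax structure, scatter and
beam-hardening, cardiac-borne motion of lung tissue near the heart,
spatially correlated noise, and patient motion. Passing recovery tests on
this generator therefore shows that the pipeline correctly extracts
amplitude-proportional cardiac-synchronous signals from additive noise —
it does not validate performance against motion artefacts or structured
clutter in clinical images.

`generate_cohort()` draws a resection cohort (default n = 52, elderly,
mostly male, lobectomy mix right upper 18 : right middle 4 : right
lower 8 : left upper 16 : left lower 6) whose measured postoperative
values equal the perfusion-weighted prediction from the *true* BFR times
`1 + ` a 10% relative Gaussian error, with independent observation noise
(SD 0.03) on the DPDR and comparator BFRs. Respiratory complications
follow `logit(p) = 1.75 − 0.05 · ppo%DLco`, chosen once so the band rates
fall roughly from ~50% below 40% ppo%DLco to under 20% above 60%;
cardiovascular events are an independent Bernoulli(0.115). The cohort is
a round-trip fixture with known error structure, not a calibrated
clinical population.

## Numerical choices

* **Zero-phase filtering.** The Butterworth coefficients come from
  `signal::butter`; the forward–backward application is vectorised over
  pixels, with odd-reflection padding of 2× the filter order and
  step-response initial conditions, so a constant series maps to zero at
  machine precision and the minimum series length is 9 frames. Finite
  sequences keep edge transients of roughly one settling length
  (~15 frames at 15 fps) at each end regardless of padding — the
  reference signal is therefore re-centred after filtering, and tests of
  waveform fidelity compare the central region.
* **Windowed correlation.** Rolling window sums come from global
  cumulative sums (column offsets cancel in the differences); the result
  matches a naive per-pixel, per-window loop to better than 1e-10 on test
  instances. Windows with temporal variance at or below `(1e-6 ×
  saturation)²` — dead or clipped pixels — yield CCv 0 with an undefined
  flag rather than an error, and edge frames where the full window does
  not fit are excluded outright (no partial windows, which would bias
  short-window correlations).
* **Ties and boundaries.** Risk-band thresholds belong to the upper band
  (exactly 70% is "≥70"). Bland–Altman limits use mean ± 2·SD with the
  n−1 SD. The degenerate zero-pooled-variance t test returns t = 0,
  p = 1 for equal means.
* **Percent-of-predicted.** No spirometric reference equation is bundled:
  predicted-normal FEV1/DLco are required inputs, and which equation
  produced them should be recorded with the cohort. This keeps the
  package agnostic to population-specific reference formulas.

## Design choices that were genuinely open

* **Pearson, not unnormalised cross-correlation.** The stated CCv range
  of −1 to 1 implies a normalised statistic; windowed Pearson correlation
  is the natural choice and makes CCv invariant to per-pixel gain and
  offset (verified by property test). No per-pixel lag search is
  performed — the reference is the single global `PC_lv`.
* **Window length.** "Frame by frame" does not fix a window; one cardiac
  period (rounded to odd, minimum 5) is the shortest meaningful choice
  and the default. The length is exposed (`window_frames`) because some
  analyses want long windows: the closed-form noise-attenuation check
  uses a full-record window, where `E[CCv] = sqrt((a²/2)/(a²/2 + σ²))`
  for amplitude `a` in noise `σ` holds without the max-over-frames bias
  that short windows introduce.
* **MaxCCv over valid frames only**, excluding nothing else: whether a
  device would trim transient frames is unknowable from the outside, so
  the implementation uses exactly the frames where a full window fits.
* **Negative MaxCCv kept in sums.** Clipping at zero is a plausible
  alternative (exposed as `clip_negative`) but is not the plain
  definition of the sum.

## Known limitations

* **BFR measures detectability, not flow.** The Pearson correlation of a
  noisy sinusoid depends on amplitude only through the signal-to-noise
  ratio, and saturates near 1 once the cardiac signal is clearly
  detectable. With a short window, the max-over-frames reduction
  saturates even faster. Consequently the recovered BFR *compresses*
  amplitude asymmetry: a lung at half the contralateral amplitude yields
  a BFR a few points below 0.5, not 0.33. The monotone relation is
  preserved (verified by the amplitude-ladder suite), but absolute
  calibration against true flow fractions would require an
  amplitude-based rather than correlation-based statistic.
* Clinical effects — beating-heart artefacts on the left lung, posture,
  and the physiological differences between radiographic pulsatility and
  capillary-bed scintigraphy — are outside the simulator, so agreement
  statistics on synthetic cohorts say nothing about inter-modality bias
  in patients.
* The full CCv stack at clinical scale (1024 × 1024 × 150 floats) is
  memory-hungry; use `store_ccv = FALSE` (the pipeline default) to keep
  only MaxCCv.

## Problem sizes used by the tests

Unit tests run at 16–32 pixel grids with 60–150 frames; the recovery
suites use the 128 × 128 × 150 default (50 symmetric replicates and a
four-rung amplitude ladder), and the cohort suites use n = 52 with 20
seeds plus one n = 10,000 law-of-large-numbers check — all chosen so the
entire suite completes in about a minute on one core.
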