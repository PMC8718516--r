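---
title: "Methods: multisensor upper-limb assessment for occupational therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multisensor upper-limb assessment for occupational therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otassess)
```

## The assessment model

`otassess` implements an instrumented assessment of upper-limb function
during occupational-therapy (OT) exercises, built from two parallel signal
paths that share one clock:

1. **Kinematic path** — a depth-camera skeleton stream (~30 Hz, jittery,
   glitch-prone) and a wearable-IMU position stream (high rate, drifting) are
   synchronized onto a uniform grid and fused per axis with a scalar Kalman
   recursion. The fused trajectory of one repetition is compared against
   healthy reference motion: both series are aligned by dynamic time warping
   (DTW), the Pearson correlation coefficient $r$ is computed per axis and
   averaged, and $r$ is mapped to an ordinal completion score,
   $$
   r(x_1, x_2) = \frac{\operatorname{cov}(x_1, x_2)}
                      {\sqrt{\operatorname{var}(x_1)\operatorname{var}(x_2)}},
   \qquad
   \text{score} =
   \begin{cases}
   3 & r \ge 0.8\\
   2 & 0.5 \le r < 0.8\\
   1 & 0.3 \le r < 0.5\\
   0 & r < 0.3
   \end{cases}
   $$
   where $x_1$ is the healthy reference and $x_2$ the patient trajectory.

2. **sEMG path** — three surface-EMG channels (forelimb, biceps brachii,
   deltoid) are band-pass filtered, reduced to an integrated-EMG (iEMG)
   activity envelope (windowed mean of the absolute signal), segmented into
   movement bursts by a recursive maximum (minimum value × length) interval
   search, and each burst — resampled to a fixed 200 × 3 matrix — is
   classified into one of four standardized OT actions by a four-branch 1-D
   convolutional network.

Cohort-level reporting correlates per-patient mean completion correlations
with clinical Lovett muscle-strength grades (0–5).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| fusion grid rate | 30 | Hz | the slower sensor's rate; resampling upward would fabricate high-frequency depth-camera content |
| variance detrend window | 0.5 | s | long enough to average noise, short enough to track volitional movement |
| Kalman `p0` | 1e-4 | m² | weakly-informative first-step prediction variance |
| iEMG window | 0.1 | s | standard EMG smoothing scale; resolves bursts ≥ 0.3 s |
| burst threshold | 0.2 | fraction of envelope max | separates burst support from the ≤ 10% inter-burst baseline with margin on both sides |
| minimum burst duration | 0.3 | s | rejects ramp fragments and glitches; real OT repetitions last seconds |
| filter band | 20–450 | Hz | the usual sEMG energy band; 50 Hz notch optional |
| classifier epochs / lr / batch | 100 / 1e-3 / 32 | — | Adam defaults; tests and the acceptance run use 30 epochs, which this generator's separability makes sufficient |
| dropout | 0.5 | — | on both fully connected layers |

## The network geometry and the pairing search

The classifier consumes 200 × 3 segments through four parallel branches
(first-stage kernels 20/16/12/8, 32 filters; 12-wide non-overlapping first
pooling; 64 second-stage filters), flattening to 1,728 features into a
128-wide hidden layer and 4 outputs. Convolutions are valid (no padding) and
kernels slide along time only; the 3-electrode axis is preserved through both
stages and re-enters at flattening (features = maps × length × 3). This is
the only channel treatment consistent with the published per-layer map sizes
— a kernel spanning the electrode depth would collapse the ×3 factor and
cannot yield the printed flatten widths (384, 384, 384, 576).

The published second-stage kernel and pooling lists admit no in-order,
non-overlapping reading that reproduces the printed map sizes
(e.g. 15 − 5 + 1 = 11, not the printed 14). `search_branch_pairing()`
enumerates all 4! × 4! kernel/window assignments under stride = window and
under every common stride 2–12; exactly one configuration reproduces every
printed size — kernels (2, 3, 4, 5) across branches, windows (5, 4, 3, 2)
with a common stride of 5 — and that configuration is the frozen default of
`textcnn_spec()`. `compute_feature_shapes()` also reports the naive in-order
reading so the discrepancy stays visible rather than silently forced.

## Kalman fusion modes

The published fusion pseudocode mixes squares and square roots
inconsistently and updates with `x = a + K (a − b)`, which moves the estimate
*away* from the IMU stream. Both readings are shipped:

* **`literal`** transcribes the pseudocode arithmetic exactly and is tested
  against an independent hand-written transcription to 1e-12. It is kept for
  auditability, not for use.
* **`standard`** (default) treats each step's IMU sample `b` as the
  prediction and the depth-camera sample `a` as the measurement with variance
  `A`. The prediction variance is the IMU variance `Z` (plus `p0` on the
  first step only). The pseudocode leaves the prediction-variance evolution
  unstated; treating `Z` as an accumulating per-step process noise instead
  would make the steady-state fused error *exceed* the better sensor's error
  whenever the sensor variance ratio exceeds about 4, defeating the stated
  purpose of the fusion. With fresh-sample prediction the gain is the
  inverse-variance weight `K = Z/(Z + A)` in steady state, every fused sample
  lies between `a` and `b`, and the fused error variance is
  `A·Z/(A + Z) ≤ min(A, Z)` — the error-reduction property the tests assert
  on 12,000-sample synthetic runs.

Sensor variances are estimated from the streams themselves by detrending
with a 0.5 s centered moving average and taking the residual variance
(corrected by `w/(w−1)` for the window-mean subtraction, with half a window
trimmed at each end where truncated windows leave trend bias). `p0`
persists per recording and is not re-initialized between repetitions.

## The burst-segmentation recursion

The published segmentation recursion scores an interval by (minimum envelope
value × interval length): at each level the minimum of the current window is
located, the whole window is a candidate, and the search recurses left and
right of the minimum. Recursing on `[ID, L]` as printed would never
terminate for `ID = 0`; the children here exclude the minimum's own index —
the only terminating reading, and precisely the classic
largest-rectangle-in-histogram recursion. It is implemented with an explicit
stack (no recursion-depth limit) and verified against O(n²) enumeration over
500 random arrays. Ties break to the leftmost, then shortest, interval.

`segment_bursts()` wraps the recursion into a detector: the channel-summed
envelope is decimated to ~50 Hz (the recursion is worst-case quadratic on
monotone stretches; decimation bounds the cost), sub-threshold samples are
zeroed, and the best interval is repeatedly selected, expanded to its full
contiguous supra-threshold island, accepted if it lasts ≥ 0.3 s, and zeroed.
Expansion to the island is what makes recovered intervals match the planted
burst support (IoU ≈ 0.95 on generator output) instead of only the
burst's high plateau.

## What the synthetic generator does and does not emulate

The generator states the world the tests live in:

* **Protocol**: 15 repetitions × 4 actions per participant; 2 s rests
  between repetitions; nine patients with the published grade pattern (four
  grade-3, four grade-4, one grade-5).
* **Actions**: natural cubic splines through hand-chosen waypoints realizing
  the four described motions (overhead lift; trembling lift with two
  intermediate lower–raise cycles; straight-arm low lift; lift with
  horizontal carry). No published coordinates exist; only the qualitative
  shape properties are asserted (e.g. action 2 has ≥ 2 interior vertical
  maxima; action 4's middle third is horizontally dominated).
* **Severity**: grade → (amplitude 1.0/0.8/0.6 for grades 5/4/3, tremor
  0/3/6 mm at 5 Hz, time dilation 1.0/1.1/1.25). The mapping is invented;
  only its monotonicity is asserted, and grades below 3 extend the same
  monotone scheme.
* **Sensors**: depth camera = 5 mm white jitter + 1% glitch spikes of 30 mm
  at 30 Hz; IMU = 1 mm jitter + 2 mm/√s random-walk drift at 800 Hz;
  timestamps share one clock origin with ±2 ms jitter (capped at 0.4 samples
  so they stay strictly increasing).
* **sEMG**: 20–450 Hz Gaussian carrier amplitude-modulated by per-action,
  per-channel envelopes (trapezoid pedestal plus action-specific effort
  bumps), baseline 4% of burst amplitude, per-repetition timing and
  amplitude jitter, severity-scaled amplitude and 5 Hz tremor modulation.

Not emulated: musculoskeletal dynamics, multi-joint skeletons,
electrode-placement variability, inter-subject anatomical variation, fatigue
drift, and real class overlap between actions 1 and 3. A green end-to-end
test therefore establishes that the pipeline's machinery is correct and
self-consistent — not that clinical accuracy (82.2% in the source cohort)
would be reproduced on real patients; the cohort behind that number is not
deposited, so the acceptance criteria are property-based stand-ins
(held-out accuracy ≥ 0.80; per-action CC–grade correlation > 0.7).

## Numerical choices and degenerate inputs

* Band-pass filtering multiplies the FFT by a Butterworth *magnitude*
  response (order 4), giving an exactly zero-phase, length-preserving filter
  with no design-package dependency; DC is removed. A Gaussian notch (1 Hz
  width) handles mains pickup.
* DTW uses absolute difference (1-D) / Euclidean (rows) local cost,
  symmetric steps, un-normalized total cost, and is exact against exhaustive
  path enumeration for short series. Correlation is computed after DTW
  alignment whenever lengths differ.
* `pearson_cc` raises an explicit error on zero-variance input rather than
  returning a silent 0; `strength_correlation` refuses all-equal grades.
* The completion rubric thresholds on signed `r` as printed; an `use_abs`
  flag scores on `|r|` for the reading in which only correlation magnitude
  matters. Negative `r` above 0.3 magnitude is undefined in the source; the
  signed table is the default.
* Multi-axis correlation is the unweighted mean of per-axis coefficients —
  the simplest faithful reading of applying the correlation to "movement
  data"; speed or norm correlation would hide axis-specific deficits.
* Multiple healthy references: mean correlation across references,
  DTW distance to the nearest; references generated at grade 5.
* Repetition boundaries for the kinematic path come from the sEMG
  segmentation when both modalities exist (one clock); otherwise the whole
  fused trajectory is assessed as a single repetition.
* Seeds: every generator and training routine takes an explicit seed and
  restores the caller's RNG state; derived per-record seeds stay below 2³¹.

## Known limitations

* The classifier is pure R (im2col + BLAS). Adequate at protocol scale
  (~540 segments train in a couple of minutes on one CPU), not for larger
  corpora.
* The `literal` fusion mode faithfully reproduces arithmetic that is not a
  credible estimator; it exists so the published recursion can be audited.
* The synthetic world is deliberately separable; reported accuracies on it
  are upper bounds, not clinical estimates.
* Which joint feeds the correlation is unstated in the source; the generator
  emits a single distal-joint stream and the choice is a configuration knob.
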