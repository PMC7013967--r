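---
title: "Gyroscope-based wrist rigidity scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gyroscope-based wrist rigidity scoring: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristrigidity)
```

## The measurement problem

Rigidity — increased resistance to passive movement — is a cardinal
parkinsonian sign, and its intraoperative reduction under trial
stimulation settings is the main feedback signal when a DBS electrode is
being positioned. The clinical grading (0–80 % improvement in decile
steps, agreed between blinded experts) is subjective and varies with the
examiner. A palm-worn gyroscope offers a physical correlate: when the
examiner imposes wrist flexions with roughly constant force, a less rigid
wrist moves faster and more smoothly. The y axis of the sensor is aligned
so that flexion appears as a *negative* arcade of angular velocity, one
arcade per imposed flexion.

The pipeline implemented here is deliberately lightweight — every step
runs comfortably on embedded hardware, which is why generic machine
learning models were never part of the design:

1. raw 16-bit counts → °/s via the full-scale mapping `w = y / 2^15 * 2000`;
2. 4-sample trailing moving-average filter on each axis;
3. strictly negative y-axis samples = flexion; maximal negative runs =
   arcades;
4. contiguous, non-overlapping windows (200 samples @ 50 Hz, or 300 @
   42 Hz on the first hardware generation);
5. per window: mean flexion velocity μω, mean peak μp (peaks =
   prominence-significant maxima between valleys), cogwheel count δ;
6. scalar descriptor φ (default `phi_R`, the product μω·μp);
7. improvement % = a·φ² + b·φ + c, fitted through the per-class mean
   descriptors of a labelled training cohort, evaluated and clamped to
   [0, 80].

The quadratic is fitted to **class means**, not raw windows: the experts'
scale is discrete and heavily tied, so the calibration curve interpolates
the central tendency of each label class, and per-window scatter is
instead summarised by the leave-one-out training error.

### Assumptions inherited from the protocol

- The imposed flexion dominates the y axis; rotations are incidental.
- The examiner's force is approximately constant across trials, so
  velocity changes reflect rigidity changes, not effort changes.
- The patient does not assist or resist; windows where this is violated
  are flagged invalid by the clinicians and excluded (`valid = FALSE`
  windows never enter class means, cross-validation, or the running best
  improvement).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| sampling rate | 50 (v2) / 42 (v1) | Hz | hardware generation |
| window size | 200 (v2) / 300 (v1) | samples | 4 s / ~7 s of movement, ≥ 2–3 arcades |
| filter width | 4 | samples | non-movement noise suppression |
| peak margin | 0.2 | °/s | minimum peak-above-valley prominence |
| cogwheel dip threshold | = margin | °/s | minimum interior rebound that counts as a catch |
| `sigma` (φ_IV only) | 1 | — | width of the Gaussian penalty on log(μp/μω) |
| tolerance | 5 | % points | accuracy criterion |

Notes on the less obvious choices:

- **Margin as prominence.** "Highest value between two valleys within a
  margin" is made operational as: a peak must rise at least 0.2 °/s above
  the minima separating it from higher ground on both sides. This single
  rule yields the valley alternation, suppresses sub-margin ripple, and
  is checked against a brute-force extrema-enumeration oracle in the test
  suite. Of two equal maxima separated by a shallow saddle, the later one
  is kept (a deterministic tie-break; ties are measure-zero on real
  signals).
- **Cogwheel detector.** The original artefact-counting procedure is not
  published in a reproducible form, so the package defines its own: within
  each arcade (delimited by zero magnitude), count one artefact per
  margin-significant hump beyond the first. It is a declared stand-in
  with the right qualitative behaviour — zero on smooth arcades, one per
  interior dip deeper than the threshold — and it is invariant under
  joint amplitude/threshold scaling.
- **σ in φ_IV** is not pinned anywhere; 1.0 makes the Gaussian factor
  penalise μp/μω ratios beyond about e, and it is exposed in every API
  that evaluates descriptors.
- **Multi-axis descriptors.** The axis-combination is implemented as a
  per-sample Euclidean norm (with the square root), so combined features
  keep °/s units; the printed formula is ambiguous on this point. Flexion
  timing for cross-axis features always comes from the y-axis sign mask,
  since only y is aligned with the flexion plane. The cross-axis sums
  `phi_xy`/`phi_xyz` multiply each axis's μω by the *y-axis* μp, exactly
  as printed, rather than by per-axis peaks.

## Numerical conventions

- **Filter edges**: the trailing mean uses a growing prefix, so output
  length equals input length and window bookkeeping is exact.
- **Order of operations** is fixed as convert → filter → flexion mask →
  window. Filtering before masking avoids creating artificial arcade
  boundaries out of noise-induced sign flips.
- **Empty or degenerate windows**: a window with no flexion samples has
  μω = μp = 0 and δ = 0; every descriptor then short-circuits to 0 with
  `valid = FALSE`, and classification reports `NA` rather than a number.
  Logarithmic descriptor forms with a zero peak mean return their
  limiting value 0 with a warning flag.
- **Fitting** requires at least three distinct class-mean points; the
  quadratic is solved by `lm()` and reproduces a closed-form
  normal-equations solve to 1e-8 in the tests.
- **Predictions are continuous** and clamped to [0, 80]; they are never
  snapped to the decile grid, because a discrete expert scale is being
  modelled by a continuous function.
- **LOOCV**: "leave-one-out with 5000 iterations" admits two readings, so
  both are provided — exhaustive (every window once, the default, exactly
  n folds) and Monte-Carlo (`iterations` seeded random holdouts). A fold
  whose holdout empties its label class is skipped and counted. Holding
  out a window only moves its own class mean.
- **Printed accuracy** is truncated (not rounded) to one decimal:
  131/156 = 83.97 % prints as 83.9 %, reproducing the convention under
  which the historical counts and the printed percentage agree.
- **Full-scale conversion**: the mapping divides by 2^15 although the
  signed register maximum is 32767; the converter therefore accepts
  magnitudes up to 32768 so the nominal full-scale count maps to exactly
  2000 °/s.

## What the simulator emulates — and what it does not

`generate_session()` produces the phenomenology the method relies on:

- flexion arcades as negative half-sine pulses at 0.75 flexions/s (the
  real arcade rate is unpublished; 0.75 Hz gives three arcades per 4-s
  window, consistent with the "2–3 arcades per window" design intent);
- peak amplitude growing linearly with improvement,
  `A(r) = 13 * (1 + 1.3 * r/80)` °/s, anchored to the published rigid
  (~13 °/s) and non-rigid (~30 °/s) mean peak values;
- cogwheel catches as brief interior notches, Poisson-distributed with a
  mean decreasing linearly through the published per-label artefact
  counts (2.6 per window at 40 % improvement, 1.2 at 80 %);
- a smaller positive extension arcade after each flexion, cross-axis
  leakage into x, and additive Gaussian sensor noise (0.05 °/s, typical
  of a MEMS rate gyroscope after low-pass filtering — necessarily below
  the 0.2 °/s margin, which exists precisely to sit above the sensor
  noise floor).

Free morphological parameters (notch depth 30–50 % of the local
magnitude, 3 % per-arcade amplitude jitter) were fixed once so that the
synthetic cohort reproduces the published operating regime — accuracy in
the low-to-mid 80s with cross-validated errors of a few points — and are
not tuned per experiment.

The simulator does **not** model examiner force dynamics, tremor
superimposed on the flexion, stimulation-voltage transients, active
patient participation, or inter-expert label disagreement. Passing tests
on synthetic cohorts therefore demonstrate the *internal* consistency of
the pipeline (features respond to amplitude and smoothness as designed,
calibration recovers known curves, the end-to-end loop attains the
intended accuracy regime on data with the assumed structure) — they are
not a clinical validation on surgical recordings, which are not publicly
available.

## Problem sizes

The test suite uses cohorts of 25 training windows per class and ~500
test windows for the end-to-end check, 200 random fixtures for each
oracle-equivalence sweep, 10⁴ random feature tuples for the descriptor
algebra, and 24 Monte-Carlo replicates per cohort size for the
coefficient-recovery rate check (25 vs 400 windows per class, expecting
the ~4× error shrinkage of a √n law). These sizes give stable statistics
while keeping the full suite under a minute.

## Known limitations

- The cogwheel counter is a reconstruction, not the original algorithm;
  δ-based descriptors (`phi_1` … `phi_8`) should be compared across
  studies with that caveat.
- Whether the historical pipeline filtered before or after discarding
  positive samples is ambiguous; this package fixes filter-first. On
  clean signals the difference is confined to arcade edges.
- Calibration transfers only within an acquisition profile: a model
  trained at 50 Hz / 200-sample windows refuses to classify a 42 Hz
  session rather than silently rescaling.
- With fewer than three represented label classes no quadratic can be
  calibrated; the fitting functions fail loudly in that regime.
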