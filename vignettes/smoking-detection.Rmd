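---
title: "Detecting cigarette smoking from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cigarette smoking from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesense)
```

## The problem and the signal model

Smoking a cigarette is a sequence of highly stereotyped arm movements.
One *sequence of puff movements* (SPM) consists of raising the hand with
the cigarette to the mouth, holding it there while inhaling, and
lowering it again. A wrist-worn inertial sensor sees this cycle twice
over: the linear accelerometer output is the vector sum of gravity and
motion acceleration, so the hand-raise both injects a transient motion
component and *re-orients the gravity vector* in the sensor frame, while
the gyroscope reports the angular rate of the forearm rotation.

`smokesense` works in the sensor frame in which, with the forearm
horizontal, +x points toward the fingers, +y to the left of the arm and
+z out of the arm; gravity at rest therefore loads the −z axis.
Acceleration is kept in g-units (hardware range ±6 g) and angular rate
in deg/s (±500 deg/s), both at a nominal 50 Hz.

Two detectors operate on this signal, followed by a common aggregation
and evaluation stage.

## Edge detection

The raw acceleration is denoised with an equiripple FIR lowpass filter
with a 1 Hz passband edge. Only the passband edge is dictated by the
method (hand movements live well below 1 Hz after gravity
re-orientation); the remaining design tolerances are package choices,
exposed through `filter_spec()`:

| parameter            | default | meaning                         |
|----------------------|---------|---------------------------------|
| `cutoff_hz`          | 1.0 Hz  | passband edge                   |
| `stopband_hz`        | 2.0 Hz  | stopband edge                   |
| `passband_ripple_db` | 1 dB    | maximum passband deviation      |
| `stopband_atten_db`  | 40 dB   | minimum stopband attenuation    |

The order is grown from a Bellanger-style estimate until the realized
Parks–McClellan response meets both tolerances (about order 110 at
50 Hz). The filter is applied as a **single-pass symmetric-FIR
convolution with exact group-delay compensation** rather than
forward–backward filtering: a linear-phase FIR is exactly zero-phase
after the integer delay shift, event times are therefore not
lag-shifted, and the realized magnitude response equals the designed
one (forward–backward application would square it, doubling the
passband deviation in dB). Signal ends are extended by edge-value
replication, so constants pass through unchanged up to the passband
ripple.

Gravity is then removed by *consecutive-sample subtraction*: between two
samples 20 ms apart the gravity contribution is essentially constant, so
`d(t) = q(t) − q(t−1)` cancels it and leaves per-sample acceleration
change due to motion. Gyroscope channels are lowpassed but not
differenced — angular rate contains no gravity term.

Edges are per-sample threshold crossings of the difference signal:
`d(t) > th` marks a rising edge (upward movement), `d(t) < −th` a
falling one. The thresholded output as printed is one-sided; falling
edges are detected symmetrically because both movement directions carry
information. One physical movement spans many samples, so runs of
same-direction detections merge into one edge mark stamped at the run's
first sample. Rising and falling edges are paired greedily (each rising
edge takes the earliest unconsumed later falling edge), and a pair
survives only if its duration lies in `[min_spm_s, max_spm_s]` —
defaults 2 and 16 s, bracketing observed puff-movement durations.
Out-of-bounds pairs are *impossible events*: both edges are consumed and
the pair discarded, which is what lets the method ignore brief erratic
gestures such as head scratches.

The detection channel defaults to the wrist sensor's z-axis
acceleration — the axis along gravity at rest, hence the axis with the
largest orientation-change signature — and the default threshold is
`th = 0.01` g/sample, roughly half the per-sample difference produced by
a typical hand-raise after filtering, and far above the residual noise
level of the filtered difference signal.

## Sliding-window SVM

The supervised detector avoids raw-signal thresholds entirely. Windows
of `w` seconds (default 10 s; 5, 15 and 20 s are natural sweep values)
are summarized by a fixed-layout feature vector: per channel the mean,
population standard deviation, maximum, minimum, peak-to-peak and RMS,
plus Pearson correlations between the accelerometer axes and between
the gyroscope axes (zero-variance pairs define correlation 0). A
radial-basis-function SVM is trained on a seeded random subsample
(default 30 %) of labelled windows; a window is labelled smoking when
its midpoint falls inside a ground-truth SPM interval. Midpoint
labelling is a package choice: it makes every positive window contain
the bulk of its SPM, at the price of boundary windows that straddle an
SPM being labelled negative despite smoke-like content.

Hyperparameters (cost from {1, 10, 100}, kernel width from
{0.25, 0.5, 1, 2}/p) are selected by minimizing the cumulative
misclassification ratio — misclassified windows over total windows —
under seeded 3-fold splitting, then the model is refit on all training
windows. Because smoking windows are a few percent of a session, the
two classes are weighted inversely to their frequency during fitting
and fold scoring; without this, an unweighted error minimizer can
ignore the positive class wholesale. Features are standardized with
training-set center and scale, which travel with the model; the
decision function is re-evaluated directly from the stored support
vectors, so a JSON-serialized model (`write_svm_model()` /
`read_svm_model()`) reproduces decisions bit-for-bit.

Detection walks a *main window* through the session in strides of `w`.
Within each main window the *small window* (same size) is evaluated at
offsets 0 and `w/2` — the package's reading of the two-shift scheme —
and if either sub-window classifies positive, one event spanning the
best-confidence sub-window is emitted. Confidence is the decision
margin (distance to the separating hyperplane), the standard
deterministic choice. All emitted events last exactly `w` seconds: the
method cannot localize event boundaries below its window granularity.
Since the offset sub-window reaches `w/2` into the next main window,
consecutive emissions can overlap; the higher-confidence event wins, so
the output stream is non-overlapping and can feed aggregation directly.

## Aggregation and evaluation

Consecutive SPMs whose idle gap (end of one to start of the next)
exceeds 600 s (10 min) are split into different cigarettes — strict
inequality, so a gap of exactly 10 min does not split. Groups with
fewer than 2 SPMs are discarded. The gap is anchored end-to-start
because it represents idle time between puffs; the count floor and gap
threshold are exposed in `aggregation_config()`.

Matching detected events to ground truth is greedy one-to-one in time
order, with interval overlap (or midpoint distance within a tolerance)
as the match criterion. For lists that are internally non-overlapping —
the only case the detectors produce — greedy matching attains the
optimal bipartite matching size, which the test suite verifies against
an exhaustive matcher. TPR is matched truth events over all truth
events. FPR needs a count of *negative instances*, which is not
well-defined for interval events; the package operationalizes it as the
number of tiled non-smoking windows (window size `w` for the SVM
method, `max_spm_s` for the edge method). ROC sweeps score one
configuration per point, and `select_best()` picks the point maximizing
TPR − FPR, breaking ties toward lower FPR, then the smaller swept
parameter.

Reported summary tables round to one decimal with half-away-from-zero
rounding (`round_half_up()`), matching how such tables are
conventionally printed; base `round()` rounds half to even and would
disagree on exact .05 boundaries. Inter-observer agreement between two
annotators' counts is `100·min/max`, averaged over items.

## The synthetic-session generator

No recorded human sessions are distributed with the package, so every
detector is validated on synthetic sessions from `simulate_session()`.
The generator emulates a laboratory protocol — `n_cigarettes` (default
6) cigarettes per session, at least 20 min apart (`inter_cigarette_s =
1200`, plus up to 120 s of uniform jitter so sessions are not
clockwork) — with topography drawn per cigarette and per puff:

| quantity            | mean | SD   | range    |
|---------------------|------|------|----------|
| puffs per cigarette | 9.2  | 3.9  | 4–21     |
| inter-puff gap (s)  | 42.7 | 21.3 | 13–110   |
| SPM duration (s)    | 5    | 2    | 2–16     |

Means, SDs and ranges of the first two rows, and the duration range of
the third, are laboratory-observed values; the SPM-duration SD of 2 s
is a package choice (unreported in the source material). Draws are
normal, clipped to the range; clipping (rather than rejection) was
chosen once for simplicity and puts small probability atoms at the
range ends, which is deliberate — boundary durations are exactly the
hard cases a duration filter must handle. All event times are snapped
to the 20 ms sample grid so that, in noise-free signals, measured
rise-to-fall spacings equal the drawn durations exactly instead of
straddling a one-sample jitter around the duration bounds.

Each SPM is synthesized kinematically: the posture interpolates from
rest (gravity on −z) to hold (gravity rotated 60° toward −x, the
hand-at-mouth posture) following a raised-cosine ramp of 0.8 s, stays
during the hold, and ramps back. The raised cosine is applied to the
*gravity projection itself*, so each axis sees a time-symmetric,
band-limited acceleration pulse; applying it to the rotation angle
instead would skew the z-axis pulse (the cosine projection changes
fastest near the hold angle), systematically shortening measured
durations by ~0.2 s. During the transitions a translational
raised-cosine pulse of 0.5 g rides on the x axis and the gyroscope's
y-axis reports the analytic angular rate (peak ≈ 120 deg/s). White
Gaussian noise (defaults 0.02 g, 2 deg/s) is added throughout, and
*confounder gestures* — fast hand-to-head bumps lasting 1–1.6 s,
outside the admissible SPM duration range — occur at 0.5/min during
rest. Puff annotations span the hold; SPM annotations span the full
movement; both carry their cigarette index. Everything is reproducible
from `sim_config(seed = …)`, with placements closer to the shoulder
(elbow, shoulder) attenuating motion amplitude.

What the generator does *not* emulate: real signal amplitudes and
spectra (unreported for the source hardware), walking and whole-body
motion, sensor drift and clock skew, repetitive confounders such as
eating, or between-participant movement styles. Passing tests on this
generator therefore demonstrate the *logic* of the pipeline — filtering
behaviour, pairing, duration filtering, grouping, scoring — not
field-ready detection accuracy; absolute thresholds tuned here do not
transfer to real hardware.

## Numerical choices and degenerate inputs

* Intervals are half-open `[start, end)` in seconds from session start,
  which prevents double counting at shared boundaries.
* A pair duration equal to `min_spm_s` or `max_spm_s` is kept
  (inclusive bounds).
* The FIR order is forced even so the group delay is an integer number
  of samples and can be cancelled exactly.
* Correlation of a zero-variance channel pair is defined as 0; feature
  standardization replaces zero scale with 1.
* Identical feature vectors carrying both labels abort training — no
  separating surface exists.
* Sessions shorter than one window classify to an empty event list with
  a warning; empty edge lists pair to empty SPM lists silently.
* `interobserver_agreement()` rejects non-positive counts, for which
  min/max agreement is undefined.

## Validation problem sizes

The test suite validates each operation against independent brute-force
oracles on 1000 random instances, and the full pipelines on simulated
sessions of 6 cigarettes (≈2.5 h of signal at 50 Hz) across 5 seeds:
noise-free sessions for exact edge-pipeline recovery, default-noise
sessions for SVM held-out rates. Generator statistics are checked on a
100-cigarette timeline sampled at 5 Hz, where only the annotations
matter. These sizes give stable statistics while keeping the default
check fast.

## Known limitations

* The SVM detector's event boundaries are quantized to the window size;
  puff-duration statistics cannot be read off its output.
* The edge detector's SPM count is not monotone in the threshold on
  noisy signals, even though the detected *edge* count is: borderline
  thresholds split threshold runs, and spurious pairs consume edges in
  the duration filter. Monotonicity of the event count is therefore a
  clean-signal property.
* Greedy event matching can in principle fall one short of the optimal
  matching when detected events overlap each other; the package's
  detectors never emit such lists.
* The two-offset reading of the main/small-window scheme is one
  plausible interpretation of a scheme whose exact semantics are
  underdetermined; both offsets and the stride are centralized in
  `window_config()` should a different reading be wanted.
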