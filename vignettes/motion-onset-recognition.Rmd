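---
title: "Recognising gait-activity onsets from three body-worn IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising gait-activity onsets from three body-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitonset` classifies, every 10 ms, which of eight gait-rehabilitation
activities a person wearing three inertial sensors (sternum, both outer
thighs) has just begun. This vignette is the package's own account of the
method: the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions taken where more than one choice was defensible.

## The recognition problem

Robotic body-weight-support devices apply task-dependent assistance; the
controller must switch modes at the *onset* of a movement, not after it has
completed. Chair transfers are the critical case: they begin with a forward
lean of the trunk before the thighs rotate, which is why one sensor sits on
the sternum. The eight classes split both transfers into an initiation
phase (`sit_to_stand`, `stand_to_sit`) and a settling phase (`m_standing`,
`m_sitting`), alongside `walking`, `turning` (180° U-turns), and the static
postures `standing` and `sitting`.

Classification operates on 100 ms windows (10 samples at 100 Hz) advanced
one sample at a time. The window must be shorter than the shortest activity
(200 ms in slow performers' settling phases), or single windows would span
two activities; it must also be short to keep recognition latency low. The
cost of so short a window is that static-vs-settling distinctions hinge on
small signal differences, which is what the orientation features are for.

## Signal model and pre-processing

Each sensor provides specific force (m/s², gravity included) and angular
rate (rad/s). The pipeline assumes:

* a uniform, synchronized 100 Hz grid across all three sensors (the I/O
  layer rejects any gap or jitter above 1 µs, because the streaming engine
  is sample-synchronous);
* an initial quiet-sitting segment of at least 0.5 s (the default
  calibration window is the first 2 s) from which constant gyroscope bias
  is estimated as the per-channel mean. A guard raises an error if any
  gyro channel's SD in that window exceeds 0.1 rad/s — a bias estimated
  over movement would corrupt everything downstream. For the
  accelerometer, only the deviation of the static mean from 9.81 m/s² is
  removed; gravity itself is the tilt reference and must remain;
* angular-rate scaling to [-1, 1] by the per-channel training-set maximum.
  The divisor is frozen with the model; inference values outside [-1, 1]
  are *not* clipped, because out-of-range rate magnitudes are exactly the
  onset information the classifier needs.

Orientation comes from a quaternion complementary filter (Hamilton
convention, scalar first, sensor-to-world): the quaternion is propagated by
the exact axis-angle exponential of each gyro increment, then rotated a
fraction `fusion_gain` of the way toward agreement with the accelerometer's
gravity direction, about a horizontal axis so that only tilt is corrected.
With `fusion_gain = 0` the filter is pure strap-down integration (its test
oracle); with gain $k$ and constant tilt-rate bias $b$ the steady-state
tilt error is about $b/(k f_s)$ — at the default $k = 0.02$ and
$f_s = 100$ Hz, a large 1°/s bias settles at ≤ 0.5°. Yaw is unobservable
without a magnetometer (deliberately unused: indoor iron disturbances); it
drifts, and no feature consumes it. The filter consumes *unscaled* rates in
rad/s; the feature extractor consumes scaled rates. The pipeline estimates
orientation before scaling — scaling is a classifier-conditioning step, not
a physical one.

## Windows, labels, balance

Windows are labelled by majority vote over their 10 per-sample labels, with
ties resolved in favour of the class occurring latest in the window
(equivalently, the last sample's class whenever that class is among the
tied modes). The tie rule is a design choice: it relabels the ambiguous
50/50 boundary windows as the *new* activity, which advances the earliest
window at which an onset can be called. Label intervals are half-open
`[start, end)` so that each sample has exactly one class and the first
sample of an activity belongs to it.

Training windows are balanced by down-sampling every class to the minimum
class count (never by duplication); test windows keep their natural
distribution, since a deployed classifier sees real class frequencies. An
optional `n_per_class` cap further sub-samples the balanced training set;
it is a problem-size control (see *Problem sizes* below), not a modelling
parameter.

## Features and selection

The default catalogue has 55 time-domain entries per window: mean, SD and
least-squares slope of the 9 scaled gyro channels (27); mean and SD of the
9 accelerometer channels (18); per-sensor accelerometer signal-magnitude
area (3); per-sensor pitch and roll means from the orientation estimate
(6); and the sternum pitch slope (1). The catalogue is a plain data frame
(`feature_catalogue()`), so a different 55-entry list can be swapped in via
configuration without touching code. Features are min–max scaled on the
training rows; constant columns are flagged and mapped to zero.

Feature selection is recursive elimination under a linear SVM: refit,
drop the feature with the smallest aggregated squared weight, repeat; then
score every candidate subset size by participant-grouped 5-fold CV accuracy
and keep the argmax (ties favour the smaller subset). Grouped folds mirror
the subject-wise testing philosophy at tractable cost. Selection runs on
scaled features — elimination by weight magnitude is only meaningful when
the columns share a scale. One property the naive intuition gets wrong, and
the test suite documents: a *duplicated* feature column is not discarded
early, because an L2 margin prefers the direction whose data scale is
doubled; what holds robustly is that pure-noise features are eliminated
before informative ones.

## The classifiers

All five families sit behind one `train_model()` / `predict()` contract so
that evaluation and streaming are model-agnostic: decision tree (Gini, no
depth cap), 3-nearest-neighbours on the scaled features, linear SVM and
linear logistic regression (both one-vs-rest in the 8-class setting, the
multiclass strategy being otherwise unconstrained), and the neural
network.

The network has a single hidden layer of 25 units (grid-searchable over
15–27 via `grid_search_hidden()`), a *soft competitive* hidden activation —
softmax across the hidden units — and symmetric-sigmoid (tanh) outputs over
the 8 classes, decoded by argmax. Targets are one-hot in {−1, +1}; the loss
is half mean squared error. This hidden/output ordering is unusual
(softmax-hidden rather than softmax-output); it is implemented as specified,
with `nn_spec(variant = "conventional")` providing the usual tanh-hidden /
softmax-output network for comparison.

Training is full-batch scaled conjugate gradient (SCG): Hessian-free
conjugate directions with adaptive scale regularisation, deterministic
given the seed, with analytic gradients (verified against numerical
differentiation in the tests). Two numerical choices matter in practice:

* **Initialisation.** A softmax-hidden net started from small random
  weights trains very slowly — all hidden units respond almost uniformly.
  The competitive variant is therefore initialised from its own structure:
  hidden unit $j$ gets weights $\beta x_j$ and bias $-\beta\|x_j\|^2/2$, so
  that the hidden softmax computes soft nearest-prototype responses
  $\mathrm{softmax}_j(-\beta\|x - x_j\|^2/2)$; prototypes $x_j$ are
  bootstrap *class centroids* (classes cycled so each of the 8 classes
  seeds at least one unit). Centroids, not raw training rows: a raw row
  carries one participant's idiosyncratic posture offsets, which the unit
  would then encode. The output layer starts from ridge regression of the
  hidden responses onto $\tanh^{-1}(0.95\,T)$. SCG then refines all
  weights jointly. $\beta = 1$ on the [0, 1]-scaled features.
* **Regularisation.** A small L2 penalty on the weights
  (`weight_decay = 1e-4`, biases free) discourages boundaries that thread
  between individual participants' posture clusters; the failure mode it
  prevents is a held-out participant's static windows landing on the wrong
  side of an over-sharp boundary.

## Evaluation

Leave-one-participant-out cross-validation re-fits *everything* inside each
training fold — gyro scale, balancing, the min–max scaler, any feature
selection, and the classifier — so the held-out participant can influence
nothing (a test shuffles and rescales the held-out data and asserts the
fitted parameters are bit-identical). Per-class metrics are one-vs-rest
from the 8×8 confusion matrix; zero-denominator cells yield zero with a
degeneracy flag. The summary reports *both* overall accuracy (trace over
total) and macro F1 (unweighted mean of per-class F1): the two are
routinely conflated in this literature, and emitting both named fields
removes the ambiguity. Macro (not weighted) averaging is used because the
per-participant summary of record is "the average of the F1-scores".
Classifier families are compared by one-way fixed-effects ANOVA on the
per-fold F1 scores with Tukey–Kramer pairwise post-hocs (valid for unequal
group sizes); 5 classifiers × 20 folds gives the familiar (4, 95) degrees
of freedom.

A stratified 70/30 window split complements LOPOCV as the biased
(subject-overlapping) comparison point; stratification is per class, within
one window.

## Streaming and the equivalence contract

The streaming engine is sample-synchronous: one logical tick per sample
(10 ms at 100 Hz). Per tick it applies the stored bias and gyro scale,
advances each sensor's orientation filter one step, appends a derived
channel row to a circular buffer, and — from the tenth sample onward —
extracts features from the chronological buffer and classifies. The
prediction is stamped with the window's last sample time (the causal
convention); for a transition beginning at sample $k$, the first window
that contains it ends at sample $k$, and full-window confirmation arrives
at $k + 9$.

Offline and streaming classification share one arithmetic path by
construction: the same filter-step function, the same per-window statistics
implemented with row-independent operations (`rowMeans`/`rowSums`
arithmetic that is identical whether the matrix holds one window or
thousands), and a deterministic per-row matrix product in the network's
forward pass. The equivalence contract is therefore *exact equality* of
label sequences, and the report treats any mismatch as a defect. An
empirical gap between separately logged offline and online runs of the
same recording is a logging artifact, not an algorithmic property, so the
package does not budget for one. A debounce utility (`debounce_track()`,
default 5 consecutive identical windows) turns the raw prediction track
into confirmed onset events for a downstream controller.

## What the synthetic cohort does and does not emulate

`generate_cohort()` realises the measurement protocol — quiet sitting,
three chair rises with settling phases, walk / U-turn / walk / U-turn,
quiet standing, final sit-down, all repeated twice — as minimum-jerk or
zero-ended sinusoid angle trajectories per sensor, converted to exact
body-frame angular rates and specific forces, plus constant gyro bias,
white sensor noise, and a fixed per-sensor mounting misalignment. Segment
durations are jittered ±10 %, scaled by a per-participant pace factor
(controls ≈ 0.9–1.1, simulated impairment 1.3–1.8 with doubled noise), and
floored at 200 ms. Nominal durations (transfers 1.5 s, settling 0.5 s,
walking bouts 3.5 s, turns 1.5 s, postures 2–2.5 s) were chosen once to
make one repetition 40 s, hence ≈ 80 s per recording; no per-class duration
statistics were available to fit beyond that total and the 200 ms minimum,
so they are stand-ins, exposed in `default_protocol()`.

The generator is deliberately *easy* relative to real recordings: it has
no soft-tissue artifact, no sensor re-seating drift, no irregular
within-segment variation of movement amplitude, no walking-aid handling
(an optional crutch-artifact flag adds sternum-roll bursts around
transfers, off by default), and its class signatures are clean by
construction. Passing the pipeline's recovery checks on this cohort
demonstrates that the machinery is correct and leak-free — not that the
reported scores transfer to clinical data.

## Problem sizes

The shipped checks run at these sizes, chosen to exercise the study-scale
design on one CPU: cohort of 20 participants (18 control, 2 impaired) at
≈ 80 s × 100 Hz each (~160,000 windows prepared once); balanced training
folds capped at 600 windows per class; SCG capped at 500 iterations for
cross-validation fits and 400 for the worked examples; RFE properties
demonstrated on planted 6-feature problems (500 windows, 100 seeded
repetitions); ANOVA size calibration on 2,000 null replicates of 5 × 20
scores. All randomness is seed-driven; identical seeds give bit-identical
cohorts, fits and predictions.

## Known limitations

* Yaw is integration-only and drifts; any feature added to the catalogue
  must not depend on absolute heading.
* The bias estimate is taken once from the initial static window; there is
  no online re-estimation, so a recording that starts mid-movement is
  rejected rather than silently mis-calibrated.
* The competitive network's prototype initialisation assumes the training
  matrix has at least as many rows as hidden units and that all 8 classes
  are present (guaranteed after balancing).
* KNN prediction cost grows with the training set; it is retained for
  comparison, not recommended for the streaming path.
* The 2 ms hardware acquisition cycle of a real-time master is below this
  engine's abstraction: the engine is sample-synchronous at the sensor
  rate, which preserves the algorithmic content but makes no wall-clock
  latency guarantees.
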