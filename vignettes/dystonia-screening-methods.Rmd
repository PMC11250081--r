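---
title: "Screening dystonic piano performance from hand kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening dystonic piano performance from hand kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Musician's dystonia (MD) is a task-specific focal dystonia that degrades
fine motor control during instrumental performance — curling or sticking
fingers at the keys — while sparing most everyday hand function.  Its
diagnosis is difficult precisely because the symptoms surface only in
the trained task.  `dscreen` implements a screening pipeline that works
from ordinary overhead video of the hands: markerless hand-landmark
trajectories are reduced to fixed-shape trial tensors, a convolutional
autoencoder trained **only on healthy pianists** scores each trial by
how poorly it is reconstructed, and trials whose reconstruction error
exceeds a healthy-calibrated threshold are flagged as abnormal.  Two
companion instruments — per-finger biomechanical function scores with a
left–right asymmetry statistic, and a temporal-order-judgment (TOJ)
staircase — probe deficits that are *not* specific to performance.

This vignette explains each model, its assumptions, and the numerical
and design choices behind the implementation.

## 1. From recordings to trial tensors

A trial consists of three files: a long-format landmark CSV
(`frame, time_s, landmark_id, x, y, z`; 21 MediaPipe-ordered landmarks
per frame at a nominal 60 Hz, normalized image coordinates), a wide
key-trace CSV (vertical displacement of all 88 keys, mm, 1 kHz,
0.01 mm quantization), and a JSON metadata record (subject, group,
hand, task 1–11, tempo, loudness).  Fixed-tempo trials must obey the
task tempo rule: 100 bpm for the single-note tasks 1–6, 80 bpm for the
chord tasks 7–11.

Preprocessing is deliberately minimal:

1. **Trial delimitation.**  The trial window runs from the beginning of
   the first keystroke to the end of the last keystroke, read off the
   key displacements.  Since no detection levels are inherent in the
   data, we use a press threshold of 0.5 mm with a release threshold of
   0.3 mm (hysteresis): well above the 0.01 mm sensor quantization and
   far below the ~10 mm full key travel, so the window is insensitive
   to the exact choice.  With the ~10 ms key attack the detected onset
   trails the physical onset by 1–2 ms.
2. **Segment extraction** keeps frames in the closed window; at least 4
   frames are required for the spline below to be determined.
3. **Hand folding.**  Performances are bimanual with mirror-image
   fingering, and one landmark file tracks one hand.  Left-hand
   trajectories are mirrored (`x -> 1 - x`) onto the right-hand frame
   so a single model serves both hands; a flag disables this.
4. **Time normalization.**  Each of the 63 landmark–coordinate channels
   is resampled independently by a **natural cubic spline** onto 128
   uniformly spaced points spanning the segment (endpoints inclusive),
   giving the 21 × 3 × 128 trial tensor.  Natural end conditions avoid
   inventing end-point curvature; interpolation is exact at the knots
   and reproduces linear channels exactly, which the tests assert.
   Every trial is normalized identically regardless of tempo condition,
   so the tensor encodes movement *shape*, not absolute speed.

**Augmentation.**  To emulate camera mounting deviations, training
tensors are rotated about the image centre and scaled anisotropically
(z untouched).  Defaults are rotation ±10° and scales 0.9–1.1 — large
relative to plausible mounting error, small enough not to distort the
kinematic content.  Augmented copies are generated **only from
training-set participants**, and validation errors are always computed
on unaugmented tensors, so the calibration below never sees leaked
copies of its own participants.

## 2. The one-class detector

The detector is a convolutional autoencoder over the landmark × time
grid with the three coordinates as input channels, chosen over a dense
autoencoder because dystonic kinematics disturb the *spatiotemporal
coordination of adjacent fingers and joints*, and convolutions preserve
exactly that adjacency structure (the MediaPipe landmark order
approximates anatomical adjacency).

* **Architecture.**  7 convolutional encoder layers and 7 convolutional
  decoder layers, 3 × 3 kernels, ReLU activations, linear output.  The
  time axis is halved at encoder layers 2, 4 and 6; layer 7 contracts
  the landmark axis (21 → 7, stride 3) and time once more, giving a
  7 × 8 bottleneck map with 32 channels (1792 numbers for an 8064-value
  input).  The decoder mirrors the encoder with nearest-neighbour
  resize + convolution, which avoids the checkerboard artefacts of
  transposed convolutions.  The channel schedule 8-16-32 keeps training
  of one model around a few minutes at the cohort sizes used here; the
  schedule, latent width and kernel are configurable.
* **Standardization.**  Inputs are centred on the training-set mean
  tensor and scaled to unit variance (both stored with the model).
  The static hand pose carries most of the signal energy but no
  diagnostic information, and the raw deviations are so small (std
  ~0.008 normalized units) that gradients would sit at the edge of the
  optimizer's numerical range; standardizing fixes both, and reported
  reconstruction errors are always mapped back to the original
  coordinate units.
* **Training.**  Adam (learning rate 1e-3, batch 32) minimizes the
  mean-squared reconstruction error; training stops when the epoch-mean
  error has not improved by more than 1e-6 for 6 consecutive epochs, or
  at 40 epochs.  All randomness (initialization, shuffling, the
  participant split, augmentation draws) is seeded independently and
  recorded in the fitted object.
* **Split.**  Healthy data are split 80/20 **by participant**, never by
  trial: reconstruction of an unseen trial from a seen participant is
  much easier than from an unseen participant, and the threshold must
  reflect the latter.
* **Calibration.**  The decision threshold is the mean reconstruction
  error of the healthy validation trials plus two standard deviations
  (sample SD, n−1).  A trial is abnormal iff its error *strictly
  exceeds* the threshold.  Under a Gaussian error distribution this
  rule concedes ≈ 2.3% false positives (specificity ≈ 97.7%), which the
  acceptance suite verifies by direct Monte Carlo.
* **Evaluation.**  Sensitivity is the proportion of patient trials
  flagged abnormal; specificity the proportion of healthy trials
  classified normal; both are reported per pianistic task, and tasks
  with sensitivity at or below the 50% chance level are flagged as
  failed classification.  One model and threshold are fitted per task
  (different tasks have different kinematic vocabularies); a pooled
  mode is available by simply passing mixed-task tensors.

Design points left open by the problem and decided here: the latent
geometry (a fully convolutional bottleneck rather than a dense layer,
keeping layer counts at exactly 7+7); per-task models rather than one
pooled model; sample SD in the calibration; and strict exceedance at
the boundary.

## 3. Biomechanical function scores and asymmetry

Six per-finger functions are scored per hand: maximum strength, the
force-reduction ratio under simultaneous all-finger exertion
(`simultaneous / maximum`), finger independence, tapping agility
(taps/s over 5 s), and two range-of-motion angles (flexion/extension,
abduction/adduction) supplied externally as degrees.

**Independence.**  During a 20%-MVC sustained hold of one designated
finger the other fingers co-contract involuntarily (enslaving).  We
quantify individuation as `1 − (sum of other fingers' force) /
(designated force)`, floored at 0, with forces summarized as the mean
over the central 3 s of the 5 s hold (the first and last second are
ramp transients).  The floor keeps the score in [0, 1]; a subject whose
enslaved force exceeds the instructed force has, operationally, no
individuation.  Note the defining ratio is deliberately
`others/designated`: the reciprocal reading would *decrease* with
better individuation and is unbounded below.

**Asymmetry.**  Because handedness and affected side vary across
subjects, group comparison uses the left–right asymmetry of each
function: with per-finger z-scores (standardized against the healthy
cohort, pooled over hands so both hands share one scale),

    Assym = || z_L − z_R ||,

the Euclidean norm over (thumb, index, middle, ring, little).  It is
zero iff the two hands have identical profiles, symmetric under hand
swap, and invariant to any common reordering of fingers.

**Statistics.**  Healthy and MD asymmetries are compared per function
by the Mann–Whitney U test with midranks; for pooled samples of at most
12 the two-sided p-value is exact (full enumeration of rank
allocations), otherwise the normal approximation with tie and
continuity correction is used.  P-values are adjusted across the tested
function family by the Benjamini–Hochberg step-up.  The exact mode is
validated against brute-force enumeration, the approximate mode against
the reference implementation in `stats`.

## 4. Temporal order judgment via ZEST

The TOJ threshold (the stimulus-onset asynchrony at which the order of
two tactile stimuli to adjacent fingertips is reported correctly 75% of
the time) is measured with a ZEST adaptive staircase: a discrete
posterior over candidate thresholds on a 61-point log-spaced grid in
[1, 500] ms.  The assumed psychometric function is a cumulative
Gaussian in log10-SOA with guess rate 0.5 (two-alternative order
judgment), slope 3 per log10-ms, lapse 0.02.  Each trial is placed at
the geometric posterior mean (snapped to the grid); the posterior is
multiplied by the response likelihood and renormalized.  This
reproduces the qualitative staircase rule — the interval shortens after
a correct response and lengthens after an error — as a theorem rather
than a rule.  Sessions run a fixed 40 trials, enough for the posterior
mean's recovery bias to fall below 10% at slopes ≥ 2; the readout is
the SOA where the posterior-mean psychometric curve crosses 75%.
Hardware stimulation is replaced by a simulated-observer abstraction
plus a trial-log replay interface for real data.

## 5. What the synthetic data emulate — and what they do not

No recordings ship with the package; the generator produces
class-separable stand-ins with the recording geometry of the real
instruments (60 Hz landmarks, 1 kHz / 0.01 mm key traces).

* **Tasks.**  Exemplar note/fingering sequences for the 11 tasks
  (scale, trill, arpeggios with and without black keys, broken thirds,
  five-finger run; thirds, repeated triads, five-note chords, octaves),
  played as sixteenths (single-note) or eighths (chords) at the task's
  fixed tempo.  The exact printed scores of the original tasks are not
  recoverable from text; these are labelled exemplars of the same
  categories.
* **Healthy trials.**  A schematic articulated right hand (wrist anchor
  plus four-joint finger chains) translates along the keyboard so the
  assigned finger reaches each key; the striking finger's chain dips
  toward the key plane in synchrony with the key excursion
  (raised-cosine profile, ~40 ms anticipation), with low-frequency
  wrist sway, per-subject style parameters (dip amplitude ~N(1, 0.08)
  scale, hand-position and timing offsets), and Gaussian landmark noise
  (SD 0.003 normalized units ≈ 4 px at 1280-px width — visible but not
  class-dominating).
* **Dystonic trials.**  On top of the healthy template for the *same
  seed*: affected finger chains (default index + middle) acquire a
  sustained flexion bias toward the key plane (0.03 units at full
  severity, weighted along the chain), lose half their strike-dip
  amplitude, jitter in strike timing (SD 20 ms), and couple 40% of the
  dip onto adjacent fingers.  Every term scales linearly with severity
  in [0, 1], so severity 0 reproduces the healthy trial bitwise and the
  kinematic distance to the healthy counterpart grows monotonically
  with severity.
* **Biomechanical cohorts.**  Healthy scores are Gaussian around a
  plausible reference (e.g. independence 0.70–0.92 by finger, strength
  26–45 N); MD subjects get a configurable SD shift on all fingers of
  the affected hand for designated functions (default −1.5 SD on the
  force-reduction ratio and independence, nothing on strength, agility
  or range of motion — mirroring deficits confined to multi-finger
  control).
* **Observers.**  Respond correctly with the assumed psychometric
  probability; with lapse 0 the location parameter is exactly the 75%
  point.

What passing tests on these data *show*: the pipeline is internally
consistent end to end — keystroke-locked windows are recovered, the
detector separates a kinematic deviation of the engineered kind and
calibrates its threshold as specified, the statistics hold their levels
and power on their stated models.  What they *cannot* show: performance
on real video, where landmark dropouts, occlusions, lighting, genuine
biomechanical diversity and subtler dystonic phenotypes are absent from
the generator.  The headline numbers reported for the original patient
cohort are properties of that cohort and are not reproducible from
synthetic data.

## 6. Numerical choices and degenerate inputs

* Natural cubic splines throughout (resampling and the hand-translation
  path); segments shorter than 4 frames are rejected rather than
  padded.
* The augmentation identity (rotation 0, scales 1) returns the input
  bit-exactly via a fast path, so augmented pipelines can be compared
  against unaugmented ones without tolerance.
* Zero-variance validation errors give threshold = mean (flagged by a
  zero SD, not an error); calibration needs ≥ 2 errors.
* Mann–Whitney with both groups identical returns U = n1·n2/2, p = 1;
  empty groups are errors, not NaNs.
* The ZEST posterior is renormalized after every update; an all-zero
  prior and out-of-grid placements are errors.  The threshold readout
  is clamped to the grid.
* All generators consume seeds through an internal child-seed scheme
  (below 2^31), never the global RNG state, and restore the caller's
  RNG.

## 7. Problem sizes used in the shipped experiments

The acceptance experiments run at deliberate desk scale: 20 healthy
subjects × 8 trials of the task-4 analogue (16 train / 4 validation
participants after the 80/20 split, 2 augmented copies per training
trial), 16 MD subjects at severity 0.8; 50 paired seeds across five
severities for the monotonicity check; 10,000 Monte-Carlo errors for
the threshold rule; 1,000 / 200 seeds for the asymmetry null and power;
100 seeds × 40 trials for ZEST recovery.  These sizes were chosen so
the full suite trains and evaluates on a single CPU in minutes while
leaving the conclusions statistically stable.

## 8. Known limitations

* The detector consumes one hand per tensor; bimanual coupling is not
  modelled.
* Whole-trial normalization discards absolute tempo; a dystonic
  slowing that is globally uniform is invisible to the detector by
  construction.
* The synthetic dystonia vocabulary (flexion bias, reduced lift,
  jitter, coupling) is a caricature of Table-style clinical patterns;
  severity grading and explainability (saliency) are out of scope.
* The biomechanical reference distribution ships as synthetic
  plausible values; real deployments should refit the reference on
  their own healthy cohort (`fit_reference()`).
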