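---
title: "Latent gait features from foot-worn IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent gait features from foot-worn IMUs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitlatent)
```

## What this package computes

`gaitlatent` analyses two-minute walk tests (2MWT) recorded with one
six-axis inertial measurement unit (IMU) per foot: a triaxial
accelerometer (range ±8 g) and gyroscope (±500 °/s), sampled at 104 Hz,
worn during back-and-forth walking on a 14-m path. Two quantities are
derived per measurement and then evaluated psychometrically:

1. **Gait speed**, from sensor-fusion orientation tracking, gravity
   removal, and integration of the horizontal acceleration with
   zero-velocity updates (ZUPT) in mid-stance.
2. **Twelve latent gait features**, the posterior means of a
   convolutional variational autoencoder (VAE) trained to reconstruct
   normalized 512-sample x 6-channel signal epochs, averaged over a
   measurement's epochs per foot.

The psychometric layer quantifies between-day test–retest reliability
(ICC(2,1) with F-based 95% CI, SEM, MDC), stroke-versus-healthy group
differences (pooled-variance t-test and Hedges' *g*), and individual
responsiveness during rehabilitation (admission-to-discharge change
against the MDC).

Because clinical recordings of this kind are not freely distributable,
the package ships a synthetic two-foot gait generator with known ground
truth; every stage of the pipeline is tested against that ground truth.

## The synthetic generator: what it emulates and what it does not

A walk is assembled from a body-level path model and per-foot stride
templates:

* **Body path.** Constant preferred speed with a 180° turn every 14 m;
  a turn lasts 1.5 s, during which speed dips smoothly to half and
  heading rotates by π (raised cosine). Turn geometry is a free
  modelling choice — the emulated protocol only fixes the path length.
* **Strides.** Stride durations are i.i.d. truncated normal with a
  per-subject mean and coefficient of variation. Each stride is stance
  (foot stationary) followed by swing; during swing, forward velocity,
  foot pitch, and vertical motion follow raised-cosine bumps scaled so
  the foot lands where the body has advanced. Smooth bump templates
  keep the ground truth analytic; no recorded waveforms are used.
* **Axis convention** (fixed once, used everywhere): x =
  anterior–posterior, y = medio-lateral, z = vertical at mid-stance;
  gravity on +z; the sagittal angular velocity is the y gyroscope.
* **Asymmetry** offsets the left/right swing fraction and swing peak by
  ±`asymmetry/2`; **sensor imperfections** are white noise, a constant
  per-axis gyroscope offset (|offset| ≤ 5 °/s, recoverable from a
  simulated static calibration), range clipping, and independent
  left/right start-time jitter up to 0.5 s (the two sensors are not
  synchronized).
* **Group templates.** Stroke-like walks are slower (0.71 ± 0.29 m/s),
  more variable and asymmetric, with a stance "shuffle" ripple and a
  sharper heel-strike transient; healthy-like walks are faster
  (1.21 ± 0.13 m/s), smoother and symmetric. The distinct template
  family is deliberate: a VAE trained on stroke-like epochs should show
  a higher reconstruction error on healthy-like epochs.
* **Sessions.** Retest (and discharge) sessions reuse the subject's
  drawn parameters plus a small session-level perturbation (e.g. SD
  0.05 m/s on speed), so test–retest agreement is high but below 1 and
  gait speed is by construction the most stable trait. The discharge
  session additionally applies a longitudinal effect (default
  +0.09 m/s, −0.02 asymmetry).

Ground truth (foot contacts, stance intervals, walked distance,
generative factors) is recorded **before** noise is added. Epochs
overlapping turns are kept, mirroring how such data are processed in
practice; some latent features can therefore encode turning.

The generator does **not** model joint kinematics, foot-drop or
shuffling sub-patterns, walking-aid signal content (aid use is metadata
only), magnetometer data, or soft-tissue artifacts. Passing tests on
synthetic cohorts demonstrate the pipeline's internal correctness and
sensitivity — not clinical validity on real recordings.

## Gait events

Supplementary material describing the original step-detection algorithm
is not available, so the detector here is fully specified and tunable
(`event_config()`): mid-swing peaks of the sagittal angular velocity
above 0.5× its 95th percentile with a 0.5-s refractory period; foot
contact at the first subsequent sample where the gyroscope magnitude
stays below the contact threshold for ≥ 50 ms; stance from contact to
the next swing onset. The contact and swing-onset thresholds default to
fractions (0.10 / 0.20) of the 95th percentile of gyroscope magnitude —
approximately 20 and 40 °/s on a typical stroke walk — which makes the
detector invariant to a common rescaling of the gyroscope signal;
absolute °/s overrides are available. Equivalence with the original
unpublished detector cannot be claimed.

## Gait speed

The speed chain preserves the conventional processing order: resample
to 100 Hz (linear interpolation; gait energy is far below the Nyquist
limit), correct the gyroscope offset from the static calibration,
detect events, estimate orientation, rotate and integrate:

* **Orientation**: quaternion propagation of the gyroscope with
  tilt correction toward the accelerometer's gravity direction, gain
  0.02 per sample during stance and 0 during swing (the accelerometer
  only measures gravity when the foot is quiet). The cited fusion
  algorithms in the underlying protocol are unspecified, so this
  complementary filter is a defined stand-in, not a claimed
  replication.
* **ZUPT integration**: trapezoidal integration of the horizontal
  global-frame acceleration to velocity; within the central 40% of
  every stance interval velocity is reset to zero, and drift is removed
  by linear de-trending across each inter-anchor span (standard
  pedestrian-dead-reckoning practice; a constant accelerometer bias is
  eliminated exactly). Distance is the sum of per-span displacement
  *magnitudes* in the horizontal plane, so the 180° heading reversals
  at turns do not cancel and no explicit anterior–posterior axis needs
  to be fixed; this also makes the estimate insensitive to slow yaw
  drift, which is unobservable without a magnetometer. Gait speed is
  distance over the covered duration (first to last anchor), which for
  a periodic walk is an unbiased estimate of mean speed.
* g = 9.81 m/s²; measurement-level speed is reported from the right
  foot (configurable).

## Preprocessing into epochs

Fixed stage order: resample → offset correction → event detection →
segmentation → band-pass filter → zero-start → outlier screening →
range normalization.

* **Segmentation**: 512-sample (5.12 s) epochs from the second to the
  second-to-last stride, starting inside a stance phase, advancing by a
  nominal 256 samples and snapping to the nearest eligible stance
  (minimum advance half a step, so stance gaps cannot stall the
  sequence) — approximately 50% overlap. By default starts snap to the
  stance-interval *start* (the foot contact), phase-locking every epoch
  to the gait cycle; snapping to an arbitrary sample inside stance
  (`snap = "stance"`) leaves up to a stance duration of random phase
  per epoch, which inflates within-measurement latent variance and
  buries subject-level structure under alignment noise. Phase-locking
  is also what makes epochs comparable across a measurement.
* **Filter**: first-order Butterworth band-pass 0.01–10 Hz, causal
  (forward-only) by default as on a wearable processing chain;
  `zero_phase = TRUE` switches to forward–backward filtering. The
  stage order places the filter after segmentation; filtering the
  whole recording first is available via `filter_scope = "recording"`
  because the conventional description is ambiguous on this point.
  Per-epoch filtering is the default.
* **Zero-start** subtracts each channel's first value, applied to all
  six channels (the only shape-consistent reading).
* **Outliers**: each epoch's per-channel mean and SD are z-scored
  against the whole epoch set; an epoch is removed when any |z| > 5,
  read two-sided. A zero-spread statistic contributes z = 0, so
  identical epochs are never removed.
* **Normalization**: symmetric min–max by the measurable ranges
  (accelerometer ÷ 8, gyroscope ÷ 500) onto [−1, 1], clamped (causal
  filtering can overshoot the hardware range negligibly).

## The VAE

Mirrored three-block convolutional encoder/decoder: kernel 3, stride 2,
tanh activations throughout, filters 32/64/128 (encoder temporal
lengths 256/128/64), a 12-dimensional Gaussian latent layer (mean and
log-variance heads), and a transposed-convolution decoder ending in a
tanh output, range-compatible with the normalized input. Strided
convolutions were chosen for the (unspecified) down-sampling mechanism,
and the decoder uses their transposed analogues; the exact
convolutional hyper-parameters behind the published architecture
sketch are not fully specified, so this reading is documented rather
than claimed identical. Adam, learning rate 0.001, batch size 64.
Training maximizes the evidence lower bound with early stopping on the
test-set loss (patience 10, min-delta 1e-5, best weights restored).

**Loss scales.** The reported `mse` is the mean over all 512×6
elements and `kl` the per-epoch KL divergence in nats (sum over the 12
dimensions, mean over the batch). The optimized objective is
`mse + kl_weight·kl` with `kl_weight = 1/3072` by default — exactly the
classic ELBO with the squared error summed over elements. A weight of
1.0 on these reporting scales would make the KL term dominate by three
orders of magnitude and drive the posterior to collapse; the chosen
default keeps both terms on the balance implied by reported
equilibria of such models (per-element MSE of a few 1e-3 against a KL
of a few tenths of a nat). Log-variances are clamped to [−15, 15] for
numerical safety; the clamp is inactive in normal training.

At inference the latent "score" of an epoch is the posterior mean (no
sampling), making all downstream psychometrics deterministic.
`make_split_plan()` builds the participant-level 70/20/10
cross-validation plan (10 folds, every subject validating exactly
once); `perturb_and_decode()` shifts one latent dimension and decodes,
the primitive for inspecting what a latent feature encodes.

Only stroke-group epochs are used for training, so the latent features
describe stroke gait; the healthy group's higher reconstruction error
is itself an outcome of interest.

## Psychometrics

* **ICC(2,1)**: two-way random-effects, absolute-agreement, single
  measurement, from the ANOVA mean squares of the n×2 matrix; 95% CI by
  the F-distribution method. Categories: < 0.5 poor, 0.5–0.75 moderate,
  0.75–0.9 good, ≥ 0.9 excellent.
* **SEM** = `sd_pooled·sqrt(1 − ICC)` with the SD of all 2n scores
  (default; consistent with published SEM/ICC pairs for gait speed);
  the `sqrt(MS_error)` variant is available via `sem_method`.
  **MDC** = 1.96·√2·SEM exactly (ratio 2.77186).
* **Group comparison**: two-sided pooled-variance t-test (Welch behind
  a flag) and Hedges' *g* with the small-sample correction
  `J = 1 − 3/(4N − 9)`.
* **Responsiveness**: per subject and feature, change is `increased`
  when delta > MDC, `decreased` when delta < −MDC, strictly — a change
  exactly equal to the MDC is not significant. By default only latent
  features with good-to-excellent reliability are evaluated (gait speed
  is always included). No multiple-testing correction is applied, by
  design; add one downstream if needed.

## Pipeline and reproducibility

`run_stage()` orchestrates simulate → preprocess → speed → train →
encode → aggregate → stats with a YAML-configurable,
schema-validated configuration; unknown keys are rejected. A single
global seed fans out to per-stage seeds by fixed offsets, every stage
writes a manifest (input/output hashes, config hash, seed), and a rerun
with the same config and seed reproduces the statistics tables
byte-identically. Epoch arrays are persisted as RDS plus a CSV
manifest at run time.

## Problem sizes used in the shipped tests

The test suite exercises the package at desk scale, chosen as the
smallest sizes at which each property is meaningfully testable: speed
recovery on 20 subjects spanning 0.3–1.3 m/s (two-minute walks);
event recovery on default-noise walks; VAE behavior on a cohort of 36
stroke and 6 healthy subjects (≈ 3,700 epochs) with half-width filters
(16/32/64) and at most 50 training epochs, on a cohort designed so
stride time and swing peak dominate between-subject variation; the
end-to-end pipeline on a miniature cohort with 30-s walks and a tiny
VAE. Unit tests of the
network use a shortened 64-sample input. Statistical conclusions about
real clinical cohorts cannot be drawn from these synthetic runs.

## Known limitations

* The event detector and orientation filter are defined stand-ins for
  unpublished clinical algorithms; no equivalence is claimed.
* The generator's turn signals and group templates are stylized;
  absolute reconstruction errors and latent structure on real data
  will differ.
* Latent features of a VAE are not identified: any rotation of the
  latent space with a matching decoder change is observationally
  equivalent, so per-dimension interpretations require the
  perturb-and-decode tool rather than the dimension index. In
  particular, factors that act multiplicatively on the waveform (such
  as an amplitude scale) tend to be encoded jointly and nonlinearly
  across dimensions rather than by a single linear coordinate, even
  when the model reconstructs them faithfully; timing-like factors
  (stride duration) align with single dimensions more readily once
  epochs are phase-locked to the gait cycle.
* Training is CPU-bound base R; it is sized for reduced desk-scale
  models, not for GPU-scale hyper-parameter sweeps (a `--latent-dim`
  override exists for manual exploration).
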