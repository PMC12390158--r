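---
title: "Methods: lumbar posture from paired trunk-worn IMUs"
author: "spinewear authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lumbar posture from paired trunk-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Two inertial measurement units taped over the thoracolumbar (T12/L1) and
lumbosacral (L5/S1) junctions each estimate their own orientation in the
Earth frame from a 20 Hz accelerometer + gyroscope + magnetometer stream.
The lumbar curvature is the *relative* orientation between them,

$$ q_{joint} = q_{L5/S1}^{-1} \otimes q_{T12/L1}, $$

decomposed as intrinsic z–y′–x″ Euler angles and reported as lateral
flexion (x), flexion–extension (y, forward flexion positive) and axial
rotation (z), in degrees.  Everything in this package exists to make that
quantity trustworthy over multi-day free-living recordings: the raw streams
carry clock skew, gyro bias, mounting misalignment and magnetic
disturbance, and the absolute angle is only meaningful relative to a
reference ("zero") posture.

The processing chain is: synchronize → remove gyro bias → fuse orientation
→ joint angles → segment standardized tasks → mask corrupted data →
normalize to a reference posture → outcome measures and repeatability.

## Clock synchronization

Each sensor has its own crystal, so nominal 20 Hz grids drift apart by
seconds over 48 h.  `estimate_clock_drift()` measures the lag between each
sensor and a reference sensor by normalized cross-correlation of the
orientation-invariant signal $|\,\lVert a\rVert - 1g\,|$ once per hour, and
fits a least-squares line to (checkpoint time, lag).  The slope is the
relative clock-speed error in samples/s; `resynchronize()` linearly
interpolates all channels onto the reference grid along that line.

Numerical choices worth knowing:

* each hourly checkpoint is placed on the highest-variance 60 s window of
  its hour, because quiet periods (sleep) carry no synchronization
  information;
* the scan range is ±10 s around the lag *tracked from the previous
  checkpoint* — accumulated drift (0.002 samples/s × 48 h ≈ 17 s) can
  exceed any fixed scan range, the hour-to-hour increment (≤ 0.15 s)
  cannot;
* a checkpoint whose correlation peak is below 0.5 is discarded;
* lags are integer samples: at 20 Hz the ≤ 1-sample residual (50 ms) is
  below anything the joint-angle computation can resolve;
* recordings shorter than two checkpoints (the ~2 h lab session) fall back
  to a single whole-record lag, the analogue of an initial
  calibration-board alignment.

## Gyroscope bias

Stillness is detected from the gyroscope alone: maximal runs with
$\lVert\omega\rVert$ below 3 deg/s lasting ≥ 5 s.  Runs longer than 60 s
are subdivided into ~60 s sub-windows; a single knot for an hours-long
sleep interval could not represent the drifting bias the piecewise-linear
model exists to capture.  Each window contributes one knot per axis (its
midpoint, its mean gyro); `eval_bias_model()` interpolates linearly between
knots and extrapolates with the nearest value, and `remove_bias()`
subtracts the result from the gyro channels only.  The accelerometer is
deliberately not consulted for stillness — a fidelity choice, since the
chain is defined on gyroscope thresholding.

## Orientation fusion and joint angles

`estimate_orientation()` runs a gradient-descent (Madgwick-type) MARG
complementary filter: the quaternion rate from the gyroscope is corrected
by descending the gravity + magnetic-field alignment objective built from
the normalized accelerometer and magnetometer.  The gain β trades gyro
smoothness against corrective pull; the default 0.1 (1/s) at 20 Hz
converges from a wrong initial orientation within ~30 s and adds < 1° RMS
on scripted noise-free kinematics.  The initial quaternion is the analytic
accelerometer + magnetometer (TRIAD-style) alignment of the first sample.
A zero-norm accelerometer or magnetometer sample degrades that step to
gyro-only integration.

The Euler sequence is intrinsic z–y′–x″ with flexion–extension as the
middle (pitch) rotation, keeping typical spine motion far from the ±90°
singularity.  Mounting misalignment is *not* corrected here — it is
deliberately left to the reference-posture stage, mirroring the chain this
package implements.

## Task segmentation

Standardized-task sessions are located in free-living data by the hop
protocol: five vertical hops precede every task.  `detect_hops()` flags
bursts where the rectified deviation $|\,\lVert a\rVert - 1g\,|$ crosses
0.5 g at least 4 times with ≥ 2 s quiet margins on both sides;
`find_task_sessions()` keeps maximal windows holding ≥ 10 bursts within an
hour.  In the laboratory, experimenter flag events define the windows
exactly.  Since a code repository cannot embed a human reviewer,
`segment_tasks()` accepts reviewed marker files verbatim and otherwise
falls back to an automatic rule: tasks in protocol order between
consecutive bursts, the last task bounded by its nominal protocol
duration, and 3-repetition tasks split into equal thirds.

## Data quality

Three exclusion rules, all strict inequalities, with every threshold a
named `pipeline_config()` key:

* **magnetic** — relative field-magnitude deviation > 30% instantaneous,
  or > 15% sustained ≥ 30 s (the whole run is flagged), or field
  inclination deviating > 30° from the reference.  Inclination is measured
  against the accelerometer gravity vector low-passed at 0.5 Hz rather
  than the fused orientation, which would be circular (the orientation
  already consumes the magnetometer).  A joint-angle sample is excluded if
  *either* spine sensor is flagged.
* **transport** — seated-transport labels dilated by ±5 min, clamped at
  the recording bounds.
* **non-physiological** — flexion > 70° or extension beyond −50°.

The expected field (magnitude, inclination) is the median over stillness
samples, ≥ 30 s of which are required unless a user reference is given;
the two spine sensors' references are cross-checked and a > 10%
disagreement raises a warning (one sensor's stillness may sit inside a
disturbance).  Exclusion fractions are reported over the full recording
after label up-sampling, with unknown-label samples in the denominator.

## Reference postures

Five strategies define "zero" for the absolute angle; all subtract
per-axis offsets over their scope:

| method | data | scope |
|---|---|---|
| lab | mean over the lab standing task | global |
| session | mean over each session's own standing task | per sensor-set session |
| day | mean over each day's standing task | per day |
| composite | median over all samples in all 12 task windows | per session |
| median_standing | median over all standing-labelled samples | per session |

Open points resolved as package decisions: the real-world *session*
reference is anchored on the first real-world standing task (day 1's); the
*composite* pools samples across windows rather than taking a median of
per-task means; *median_standing* excludes stepping and masked samples.
Range of motion is mathematically invariant to any constant offset, so it
is computed from the pre-reference angles — the invariance is then exact
rather than up to floating-point rounding.

## Outcomes and repeatability

Per task and condition: ROM (max − min over unmasked samples, on the
task's primary axis, averaged across the three repetitions) and starting
posture (mean of the first five unmasked samples, flexion axis).
Repeatability across the three conditions (lab, real-world day 1 and
day 2 — jointly a sensor-set × time-point factor) is ICC(A,k), the two-way
random-effects, absolute-agreement, average-measures intraclass
correlation,

$$ \widehat{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}, $$

with rows = participants after listwise deletion, interpreted as poor
(< 0.5), moderate (0.5–0.75), good (0.75–0.9), excellent (> 0.9).
Negative estimates are reported as-is.  F-based confidence intervals are
available (`icc_2k_ci()`) but are not part of any acceptance check.

## What the synthetic cohort emulates — and what it does not

`make_cohort()` realizes the generative model the pipeline must invert:

* a 12-task scripted protocol (minimum-jerk trajectories, 5 s end-range
  holds, five 2 g half-sine hops of 150 ms before every task) performed
  once in the lab and once per real-world day;
* free-living filler as a semi-Markov chain over sitting / standing /
  stepping / lying / seated transport with per-activity postures
  (transport is kept clear of the scripted session — participants perform
  the tasks at home);
* participant structure: neutral posture ~ N(10°, between-participant
  s.d.), a per-condition behavioral offset, and a participant × task
  "style" effect constant across conditions.  The style term matters: it
  is the task-specific individuality that survives session-level
  normalization.  Without it every session-scoped reference would remove
  *all* between-participant variance and no method could show
  repeatability — unlike real cohorts, where people differ in how they
  sit, slump and bend beyond a single global offset;
* measurement corruption: per-sensor clock skew (uniform in ±0.002
  samples/s ≈ seconds over 48 h), slowly drifting gyro bias, per-sensor-set
  mounting misalignment (the lab set and the real-world set are different
  physical sensors), white sensor noise, and magnetic disturbances —
  instantaneous steps (> 30%), sustained 15–30% offsets of ≥ 40 s, and
  inclination tilts — drawn to cover a target fraction of the day.

The population ICC(A,k) of true starting postures follows from the
`cohort_spec()` variances: for a given task,
$(\sigma_b^2 + \sigma_{style}^2) / (\sigma_b^2 + \sigma_{style}^2 +
\sigma_w^2 / k)$.

Not emulated: soft-tissue artifact, multi-segment kinematics,
temperature-dependent bias, magnetometer hard/soft-iron distortion beyond
the scripted field changes, and realistic circadian activity structure.  A
green test therefore establishes that the *algorithms invert the stated
error model*; it does not certify accuracy on human recordings, whose
disturbances are richer.

Scale: the stated world has 86400 s days; tests and examples use 900–1800 s
days to stay within compute budgets (the clock-drift recovery check runs at
the full 48 h).  Day length only dilutes free-living filler; every
per-stage property is length-invariant.

## Known limitations

* Long magnetic disturbances are excluded, not corrected; with the
  magnetometer gone, heading error grows without bound, which is why no
  distortion-robust fusion variant is offered here.
* The automatic task segmentation assumes protocol order; deviations
  require a marker file.
* The ICC(A,k) point estimator carries the standard downward small-sample
  bias of ANOVA-ratio estimators (about −0.12 at n = 17 for a population
  value of 0.3); the acceptance suite checks the estimator against a
  distribution-level oracle of its finite-sample expectation rather than
  pretending the bias away.
* Sub-sample (fractional) lags are not estimated; 50 ms residual alignment
  error is accepted by design.
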