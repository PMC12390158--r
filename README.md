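# spinewear

Lumbar spine posture and movement from paired trunk-worn inertial
measurement units (IMUs), in the laboratory and in daily life.

## The problem

Optical motion capture measures spinal posture well, but only in a lab.
Small IMUs taped over the thoracolumbar (T12/L1) and lumbosacral (L5/S1)
junctions can record for days — at the cost of a chain of error sources
that a desk analysis must invert:

* independent sensor clocks drifting seconds apart over 48 h;
* slowly drifting gyroscope bias, the dominant cause of orientation drift;
* magnetic disturbance (buildings, vehicles, mattress springs) corrupting
  the magnetometer that anchors heading;
* mounting misalignment that changes every time sensors are (re)attached,
  making the *absolute* angle meaningful only relative to a reference
  ("zero") posture.

The lumbar angle is the relative orientation of the two spine sensors,
`q_joint = q_lower⁻¹ ⊗ q_upper`, reported as lateral flexion (x),
flexion–extension (y, flexion positive) and axial rotation (z) in degrees.
The package implements the full chain — cross-correlation clock
synchronization with linear drift correction, stillness-based
piecewise-linear gyro-bias removal, a gradient-descent (Madgwick-type)
MARG orientation filter, hop-burst task segmentation, magnetic / transport
/ non-physiological data exclusion, five reference-posture strategies, and
repeatability via the two-way random-effects absolute-agreement
average-measures intraclass correlation ICC(A,k) — plus a synthetic-cohort
generator with known ground truth so every stage is verifiable without
human recordings.

## Worked example

Simulate a 17-participant cohort in which the lab and real-world sensor
sets carry different mounting offsets (s.d. 6°) and behaviour barely
changes between days, then compare the five reference strategies:

```r
library(spinewear)

spec <- cohort_spec(n_participants = 17, within_sd_deg = 1,
                    mount_sd_deg = 6, day_s = 900,
                    disturbance_density = 0, seed = 110)
cohort <- make_cohort(spec, level = "angles")
conds <- cohort_conditions_from_truth(cohort)

for (m in c("lab", "session", "day", "composite", "median_standing")) {
  normed <- lapply(conds, function(cc)
    apply_reference(cc, compute_reference(m, cc)))
  rep <- repeatability_report(outcome_table(normed), "start")
  cat(sprintf("%-15s mean start-posture ICC %.2f (sd %.2f)\n",
              m, attr(rep, "mean"), attr(rep, "sd")))
}
#> lab             mean start-posture ICC 0.86 (sd 0.04)
#> session         mean start-posture ICC 0.91 (sd 0.29)
#> day             mean start-posture ICC 1.00 (sd 0.00)
#> composite       mean start-posture ICC 0.99 (sd 0.01)
#> median_standing mean start-posture ICC 0.95 (sd 0.03)
```

The lab reference scores lowest: it is estimated on the lab sensor set and
leaves the real-world set's mounting offset inside both real-world days.
Session-scoped references (composite above all, which pools all 12 task
windows) remove the per-set offset and recover the repeatability that is
really there.  Range-of-motion outcomes are bit-identical under every
method — a constant offset cannot change max − min.

The single statistic behind those rows:

```r
x <- simulate_icc_cohort(n = 17, k = 3, icc_k = 0.7)
icc_2k(x)
#> ICC(A,3) = 0.752 (good; n = 17)
```

And the full raw-stream pipeline (sync → bias → fusion → segmentation →
quality → references → ICC), on generated IMU files:

```r
cohort <- make_cohort(cohort_spec(n_participants = 4, day_s = 1200,
                                  disturbance_density = 0.1, seed = 42),
                      level = "imu")
res <- run_pipeline(cohort, pipeline_config(seed = 42))
res$conditions$P01$rw1$mask
#> <quality_mask> magnetic 13.0%, transport 0.0%, non-physiological 0.9%,
#>   union 14.0% of 23999 samples
```

The magnetic fraction tracks the injected disturbance density; the
manifest (`res$manifest`) records parameters, seed and per-stage sample
counts for every artifact written.

A command-line interface wraps the same stages
(`inst/cli/spinewear simulate | run | icc | qc`).

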