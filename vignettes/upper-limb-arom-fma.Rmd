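---
title: "Measuring upper-limb AROM and scoring motor performance from skeleton streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring upper-limb AROM and scoring motor performance from skeleton streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinarom)
```

## The measurement problem

Clinical monitoring of children with spastic hemiparesis relies on the active
range of motion (AROM) of the shoulder and elbow and on ordinal motor scales
such as the Fugl-Meyer upper-extremity assessment (FMA). A markerless depth
sensor that streams a 25-joint skeleton at 30 Hz can measure joint angles
without touching the patient, and can therefore automate the angle-measurable
part of the FMA while a therapist scores the rest. `kinarom` implements that
measurement chain — joint angles, AROM session summaries, semi-automated FMA
scoring, capacity classification and group comparison — together with a
forward-kinematics simulator that stands in for the physical sensor, so every
stage is testable at a desk.

## Joint angles: the two-vector included angle

Every movement is measured as the included angle at a vertex joint between a
proximal segment vector $V_p$ and a distal segment vector $V_d$:

$$\cos\theta = \frac{V_d \cdot V_p}{\lvert V_d\rvert\,\lvert V_p\rvert},$$

with the cosine clamped into $[-1, 1]$ before the arccosine for
floating-point safety, giving $\theta \in [0^\circ, 180^\circ]$. The joint
triples are: shoulder abduction (Hip, Shoulder, Elbow; vertex Shoulder),
shoulder adduction (Hand, Shoulder, Hip), elbow flexion (Shoulder, Elbow,
Hand; vertex Elbow), elbow extension (Hand, Elbow, Shoulder). "Hand" is the
hand joint of the skeleton layout, not the wrist or the hand tip; the triples
are configurable in `segment_definition()`.

Two conventions deserve emphasis:

* **Full 3D angle, no projection.** Abduction is performed in the frontal
  plane and elbow flexion in the sagittal plane, but that describes the
  movement, not a computation step: the formula above contains no projection,
  so the package computes the full spatial included angle. A `project`
  argument (`"frontal"`, `"sagittal"`) is exposed on `joint_angle()` purely
  for sensitivity analysis.
* **Included-angle convention for the elbow.** 180° means a straight arm;
  flexing reduces the angle. This matches the fixed-angle bench table, which
  reports elbow references up to 180°, and differs from the anatomical
  convention in which 0° is straight.

Both $V_p$ and $V_d$ point *away* from the vertex. This is the only
orientation convention under which an arm abducted to the horizontal measures
90°, which fixes the choice.

Frames in which any required joint is `not_tracked` are excluded from the
series and listed with a reason; an angle computed through a missing joint
would be meaningless. The adduction triple (Hand, Shoulder, Hip) is
hand-referenced and anatomically unusual; it is implemented as specified but
the default assessment path uses abduction, flexion and extension.

## From a session to an AROM value

A measurement session is 30 frames (one second at 30 Hz) of a voluntary
movement. The reduction to a single AROM value is deliberately simple:

1. **Running-median smoothing**, centered window of 5 frames (configurable,
   odd; 1 disables smoothing). At the edges the window shrinks symmetrically
   to fit. The median suppresses single-frame spikes — the "flying pixel"
   artefacts of time-of-flight depth sensing — without ever widening the
   range of the series.
2. **AROM = maximum of the smoothed series.** The active limit of a movement
   is the largest angle actually reached; the maximum of a median-smoothed
   series captures it while staying robust to isolated spikes. Because a
   session-value definition of "the" AROM could also plausibly be the mean,
   `extract_arom()` reports the mean and sample SD (denominator $n-1$)
   alongside, so either reduction can be compared.

Accuracy against a goniometer reference is expressed per fixed angle as the
absolute error $\lvert \bar\theta - \theta_{ref}\rvert$ (3 decimals) and the
relative error $100\,\lvert\bar\theta - \theta_{ref}\rvert/\theta_{ref}$
(2 decimals). Clinical tables in this package round half-up; the bundled
bench table's printed relative errors follow truncation to 2 decimals, so
`accuracy_row()` exposes both modes. One row of the bundled table (right
shoulder at 60°) carries a 0.001° inconsistency between its printed mean and
its printed error; the package recomputes from the mean and does not chase
the printed error there.

## Semi-automated Fugl-Meyer scoring

The upper-extremity motor FMA has 33 items scored 0/1/2, maximum 66. Thirty
items — reflexes, rotation, pronation/supination, wrist, hand, grip,
coordination — cannot be derived from the 25-joint stream and stay manual.
The three flexor/extensor-synergy items that reduce to a reachable angle are
automated: shoulder abduction, elbow flexion and elbow extension (section
A-II, "voluntary movement within synergies"). This particular split (3
automated of the 9 A-II items) is the package default and is configurable;
the item identities are a design choice, since 33 − 30 fixes only their
count.

Each automated item maps measured AROM to the ordinal via two cutoffs:
score 2 at or above `full`, 1 at or above `partial`, 0 below. Defaults
(degrees, included-angle convention for the elbow):

| movement | partial | full |
|---|---|---|
| shoulder abduction | 90 | 150 |
| elbow flexion | 60 | 130 |
| elbow extension | 120 | 160 |

No published angle-to-ordinal cutoffs exist for this instrument, so the
defaults sit at clinically typical partial/full ranges and are overridable
per clinic (`a2_default_thresholds()` or a JSON config in the CLI).

Total scores classify into capacity bands. Published descriptions of the
bands disagree at two points (31/32 and the 48–52 range), so three schemes
are provided: `interface` (0–22 none, 23–31 low, 32–47 limited, 53–66 total,
48–52 unclassified), `discussion` (31–47 limited, 47–52 notable, 52–66 total
with shared endpoints resolved upward), and the default `hybrid`, a
half-open-interval partition — $[0,23)$ none, $[23,31)$ low, $[31,47)$
limited, $[47,52)$ notable, $[52,66]$ total — chosen because it is the only
scheme that both partitions the scale without gaps and reproduces the
published 78% "total capacity" share of the bundled study cohort.

## The motion simulator

`pose_to_skeleton()` places a seated child-scale template in camera space
(x to the camera's left, y up, z toward the participant, origin at the
sensor; this axis convention is an assumption isolated in one function) and
articulates one arm by forward kinematics:

* abduction rotates the shoulder→hip direction laterally *within* the
  frontal plane of the template, so the measured included angle equals the
  prescribed abduction exactly;
* elbow flexion bends the forearm toward the camera in the plane spanned by
  the upper arm and the camera axis, so the measured elbow angle equals the
  prescribed included angle exactly.

Zero-noise round trips through `joint_angle()` recover prescribed angles to
~1e-12°, which is the basis of the 200-pose acceptance property (< 1e-6°).

Default anthropometry (upper arm 0.28 m, forearm+hand 0.30 m, shoulder-hip
drop 0.40 m, shoulder half-width 0.18 m) is child-scale and configurable; no
published segment lengths accompany the protocol.

**Noise model.** Sensor error is characterised empirically at the angle
level: a bench measurement of a fixed 90° pose at distances of 1/2/3 m and
illuminances of 7/73 lx gives six (bias, SD) presets — e.g. +1.65° ± 2.06° at
the recommended 2 m / 73 lx, and a large +21.32° bias at 1 m / 73 lx where
the field of view clips the scene. `condition_noise_params()` treats these
as an empirical lookup (no mechanistic illumination model is attempted).
Simulation injects `bias + N(0, sd)` into each movement angle *in its
movement plane* (the pose is re-articulated at the perturbed angle, clamped
to [0, 180]°), then adds small isotropic positional jitter (default 0.003 m)
to every joint so downstream code sees realistic, non-planar coordinates.
Because the jitter adds its own angular variance (~0.9° at these segment
lengths), self-consistency checks of the angular path set the jitter to zero.
The clamp can bias re-measured angles at the extremes of the scale; checks
are therefore run at 90°, far from the clamp.

`simulate_cohort()` generates the study conditions: two groups of children,
per-side true abduction AROM and elbow-flexion limits drawn from
control 108.51 ± 19.67 / study 81.60 ± 26.94 (abduction) and
100.85 ± 37.88 / 116.15 ± 44.09 (flexion, included angle), manual-item
profiles targeting totals of 65 ± 1 (control) and 56 ± 10 (study), and one
30-frame constant-pose stream per movement and side at the 2 m / 73 lx
preset — the held-limit protocol, in which the participant holds the reached
limit while 30 samples accumulate. Ground-truth angles are retained on every
record for recovery tests.

**What the simulator does not emulate:** occlusion and limb self-crossing,
depth-image artefacts beyond their net angular effect, skeleton-fitting
failures correlated across joints, soft-tissue and clothing effects, tremor
spectra, or within-session fatigue. Passing tests therefore validate the
*computational chain* (geometry, reduction, scoring, statistics) and the
noise-injection path's self-consistency — not the physical sensor's accuracy,
which only the bench table and cohort datasets speak to.

## Statistics

Group comparisons use the Wilcoxon rank-sum test (equivalently the
Mann-Whitney U), two-sided, α = 0.05. The implementation uses mid-ranks for
ties and two methods:

* **exact**: enumerates all $\binom{n_x+n_y}{n_x}$ assignments of the pooled
  mid-ranks and computes $p = P(\lvert W - \mu_W\rvert \ge \lvert w_{obs} -
  \mu_W\rvert)$ under that symmetric permutation distribution. Chosen
  automatically for $n_x + n_y \le 16$; verified against an independent
  bitmask brute-force enumerator.
* **normal approximation**: tie-corrected variance
  $\frac{n_x n_y}{12}\bigl(N + 1 - \frac{\sum(t^3 - t)}{N(N-1)}\bigr)$ with a
  0.5 continuity correction; numerically identical to
  `stats::wilcox.test(exact = FALSE, correct = TRUE)`, which serves as the
  cross-check in the test suite.

At very small samples the exact two-sided p is granular (steps of
$1/\binom{N}{n_x}$), so exact and approximate p agree closely only in the
decision-relevant tail; the test suite asserts agreement within 0.05 for
p < 0.1 rather than a blanket bound.

Summary statistics use the sample SD (denominator $n-1$; the bundled study
cohort's age column reproduces 8.28 ± 2.32 under this convention, which
fixes it) and half-up rounding to the reported decimals (e.g. the 77.78%
total-capacity share prints as 78%).

## Degenerate inputs and numerical choices

* Segment vectors shorter than 1e-9 m raise a degenerate-geometry error
  rather than returning an angle.
* `validate_frame()` is total: arbitrary junk yields issue descriptors,
  never an error.
* Streams must have strictly increasing frame indices; missing timestamps
  are derived as `frame_index / rate`.
* All simulators take an explicit integer seed; identical seeds give
  bit-identical streams and cohorts.
* Smoothing windows wider than the series shrink to the largest odd width
  that fits.

## Problem sizes

The test suite and the acceptance script run simulations sized for seconds,
not hours, while keeping Monte-Carlo error well below the tolerances they
assert: 200 random poses for the forward-kinematics round trip, 40 random
small-sample cases for the exact-test oracle, 1000 replicate 30-frame
sessions per noise preset (30 000 angle samples each, Monte-Carlo SE of the
mean ≤ 0.033°) for the self-consistency check, and 5–18 participants per
group for pipeline-level tests.

## Worked example

```{r, eval = FALSE}
library(kinarom)

# one abduction session at the recommended acquisition condition
stream <- simulate_measurement_session(
  arm_pose("right", shoulder_abduction = 95),
  noise = condition_noise_params(2, 73), seed = 42)
series <- angle_series(stream, "shoulder_abduction", "right")
extract_arom(series)

# the bundled 18 + 18 cohort: classification shares and group comparison
bundle <- run_pipeline(read_cohort())
bundle$shares$study
bundle$comparisons
```

## Known limitations

* Shoulder rotation, pronation/supination and wrist angles are out of scope:
  the 25-joint stream cannot resolve them, which is exactly why 30 FMA items
  stay manual.
* The automated-item cutoffs are defaults, not validated pediatric norms.
* The published group comparison of FMA totals is not exactly reproducible
  from the published per-participant table (the printed group SDs disagree
  between summary tables); the package reports what the data it is given
  yields, and the rejection decision at α = 0.05 is unaffected.
* The noise presets are condition-specific empirical constants; interpolating
  between them is not supported by the data and is refused rather than
  guessed.
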