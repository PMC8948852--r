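# kinarom

Semi-automated assessment of upper-limb motor performance in children from
markerless 25-joint skeleton streams (Kinect-v2 layout, 30 Hz).

Rehabilitation monitoring of children with spastic hemiparesis needs two
quantities: the **active range of motion (AROM)** of the shoulder and elbow,
and the **Fugl-Meyer upper-extremity motor score (FMA)** — 33 ordinal items
scored 0/1/2, maximum 66. A depth sensor's skeleton stream can measure joint
angles without touching the patient, which automates the three
flexor/extensor-synergy FMA items that reduce to a reachable angle (shoulder
abduction, elbow flexion, elbow extension) while a therapist scores the
remaining 30. `kinarom` implements that whole chain, plus a
forward-kinematics simulator of noisy seated measurement sessions that
replaces the physical sensor, so the pipeline is fully testable at a desk.

## The core computation

Every movement angle is the included angle at a vertex joint between the
proximal and distal segment vectors,

    cos θ = (V_d · V_p) / (|V_d| |V_p|),       θ ∈ [0°, 180°]

with movement-specific joint triples (abduction: Hip–Shoulder–Elbow with the
shoulder as vertex; flexion: Shoulder–Elbow–Hand with the elbow as vertex;
elbow angles use the included-angle convention, 180° = straight). A
measurement session (30 frames at 30 Hz) reduces to

    AROM = max( running-median₅(θ₁, …, θ₃₀) ),

robust to single-frame depth-sensor spikes. Automated FMA items map AROM to
0/1/2 through configurable partial/full angle cutoffs; totals classify into
capacity bands (default partition: [0,23) none, [23,31) low, [31,47) limited,
[47,52) notable, [52,66] total); groups are compared with a two-sided
Wilcoxon rank-sum test (exact enumeration with mid-ranks for small samples,
tie-corrected continuity-corrected normal approximation otherwise).

The simulator articulates a seated child-scale template by forward
kinematics (zero-noise poses re-measure to < 1e-6°) and injects calibrated
angular noise per acquisition condition — six empirical (bias, SD) presets at
{1, 2, 3} m × {7, 73} lx, e.g. +1.65° ± 2.06° at the recommended 2 m / 73 lx
— followed by isotropic positional jitter.

## Worked example

```r
library(kinarom)

# one simulated abduction session, true limit 95°, 2 m / 73 lx condition
stream <- simulate_measurement_session(
  arm_pose("right", shoulder_abduction = 95),
  noise = condition_noise_params(2, 73), seed = 42)
extract_arom(angle_series(stream, "shoulder_abduction", "right"))
#> <arom_result: shoulder_abduction/right arom=98.34 mean=95.88 sd=1.63 n=30 (+0 excluded)>
```

The session mean 95.88° reflects the true 95° plus the condition's +1.65°
systematic bias; the AROM (max of the smoothed series) sits a couple of
degrees above the mean, as expected for the maximum of 30 noisy samples.

```r
# bundled 36-child example cohort (18 control + 18 study, pre-assessed totals)
bundle <- run_pipeline(read_cohort())
bundle$shares$study
#>   category count percent
#> 1     none     0       0
#> 2      low     0       0
#> 3  limited     3      17
#> 4  notable     1       6
#> 5    total    14      78
bundle$comparisons
#>       label n_a mean_a sd_a n_b mean_b sd_b u_statistic      p_value h0
#> 1 fma_total  18     65    1  18     56   10         281 0.0001419959  1
```

78% of the study group reaches total upper-limb capacity (total ≥ 52), and
the control/study difference in FMA totals is significant at α = 0.05
(`h0 = 1` means the no-difference hypothesis is rejected).

A thin CLI over the same functions ships in `inst/cli/kinarom`
(`simulate`, `angles`, `arom`, `score`, `compare`, `pipeline`).

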