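# gaitrig

Markerless gait analysis with a rig of consumer depth sensors, validated the
way clinical gait labs validate new instruments: against a reference optical
motion-capture system, step by step.

A single depth sensor tracks a 25-joint skeleton at ~30 Hz but covers only a
few meters, so walking trials need several sensors whose data must be merged.
`gaitrig` implements the full desk-scale pipeline:

1. **Extrinsic calibration** — every sensor's pose in one global frame is
   estimated from flat printed markers. Each sighting gives a rigid
   (Kabsch/Procrustes) fit of the marker's known corner template onto the
   observed corners; the "sensor *s* sees marker *m*" relation forms a
   bipartite visibility graph, and each sensor's pose is the concatenation
   of fitted Euclidean transforms along its shortest path to the origin
   marker. A point-to-point ICP pass over overlapping point clouds refines
   the chained poses.
2. **Skeleton fusion** — per-sensor skeleton streams are mapped into the
   global frame, linearly resampled onto one fixed 30 Hz grid, averaged with
   equal weights over the sensors that track each joint (untracked and
   inferred joints are missing data), and low-pass filtered (zero-phase
   Butterworth, order 4, 6 Hz).
3. **Gait parameters** — foot events are the crossings of the two ankles'
   forward positions; at each crossing the stance ankle sits on its stance
   plateau, which *is* the foot placement. From the placement sequence:
   step length, step width, step time, stride length, and walking speed
   = Σ step length / Σ step time. The first left step and first right stride
   (gait initiation) are excluded. The identical procedure runs on
   reference-system ankle trajectories.
4. **Agreement statistics** — paired system-vs-reference values are
   summarised per parameter, side and aggregation level with Pearson's *r*,
   Bland–Altman bias = mean(d), RPC = 1.96·sd(d), CV = 100·sd(d)/grand mean,
   and the two-way absolute-agreement single-measure intraclass correlation
   ICC(A,1) = (MS<sub>R</sub> − MS<sub>E</sub>) / (MS<sub>R</sub> +
   (k−1)MS<sub>E</sub> + (k/n)(MS<sub>C</sub> − MS<sub>E</sub>)), classified
   as poor/fair/good/excellent.
5. **Simulator** — a parameterised walker (stance plateaus, raised-cosine
   swings, commanded step length/width/cadence) plus a configurable sensor
   rig generate every input with known ground truth: marker observations,
   point clouds, and skeleton streams corrupted by joint noise, clock
   jitter, frustum culling, self-occlusion dropout and a view-side lateral
   surface-pull bias. Everything the pipeline reports can therefore be
   checked against construction.

## Worked example

```r
library(gaitrig)
set.seed(1)

rig     <- simulate_rig()              # 3 rows x 2 sensors, 35 deg inward
markers <- default_marker_poses()      # floor markers along the corridor
obs <- simulate_marker_observations(rig, markers, noise_sigma = 0.005, seed = 1)
cal <- calibrate_rig(obs)
glance(cal)
#>   n_sensors max_path_length mean_rms n_refined
#> 1         6               5  0.00593         0
```

Six sensors calibrate; the farthest pair chains through five graph edges
with a 5.9 mm mean corner residual at the injected 5 mm corner noise.

```r
truth   <- simulate_gait(step_length = 0.73, step_width = 0.12, cadence = 100)
streams <- corrupt_streams(truth, rig, joint_noise_sigma = 0.01, seed = 2)
fused   <- smooth_series(fuse_streams(streams, subset = "both"))
gp      <- analyze_gait(fused)
gp
#> <gait_parameters> 10 steps, 9 strides, walking speed 121.81 cm/s
```

The commanded walk (73 cm steps every 0.6 s → 121.67 cm/s) is recovered at
121.81 cm/s from noisy, occluded, multi-sensor streams. Comparing three such
recordings against the reference analysis of the same walks:

```r
at <- agreement_table(system_params, reference_params)
writeLines(format_agreement_table(at))
#> Parameter             Mean±SD (A)   Mean±SD (B)   R      P       N   Bias   RPC   CV (%)  ICC(A,1)  Category
#> Step length L (cm)    72.72 ±3.97   72.64 ±4.14   0.993  <0.001  14  0.08   1.00  0.70    0.992     excellent
#> Step length R (cm)    72.73 ±4.42   72.69 ±4.27   0.991  <0.001  16  0.05   1.18  0.83    0.991     excellent
#> AV step width AVG (cm) 12.13 ±1.61  12.33 ±1.53   1.000  0.004   3   -0.20  0.16  0.66    0.991     excellent
```

Per-step agreement is excellent; the `AV`/`AVG` rows aggregate per subject
and across feet, mirroring the standard reporting layout of gait-validation
studies. Reconstructing the same recordings with `subset = "left_only"`
instead of `"both"` exposes the cost of one-sided tracking — larger
step-width RPC and lower ICC — while two-sided fusion also cancels the
view-side lateral surface-pull bias by symmetry.

A command-line wrapper (`inst/scripts/gaitrig`) exposes `simulate`,
`calibrate`, `fuse`, `gait`, `agree` and `run` subcommands over the same
functions, configured by a YAML file with `--set key.path=value` overrides.

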