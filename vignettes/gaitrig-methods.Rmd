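---
title: "Methods: multi-sensor gait analysis, from calibration to agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitrig)
```

`gaitrig` validates a markerless gait-analysis rig built from flanking depth
sensors. This vignette documents the models and procedures, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Extrinsic calibration

Each sensor reports 3D coordinates in its own local frame. Calibration
estimates one rigid transform (proper rotation + translation; never scale or
reflection) per sensor into a global frame defined by a designated origin
marker lying flat on the floor: its plane spans the horizontal axes, its
first in-plane edge is the walking-direction X axis, and its normal is Z-up.

The estimation chain is:

1. **Per-sighting Procrustes fit.** A marker's corner template
   (`marker_template()`, four corners of a square, counter-clockwise from
   the dent corner, side 0.30 m by default) is rigidly fitted onto the
   observed corners with the SVD (Kabsch) solution; the sign of the smallest
   singular value is corrected so reflections are impossible, and scaling is
   structurally excluded — a scaled point set simply leaves a large
   residual, which the tests assert. Fits with fewer than three
   non-collinear points are rejected (the in-plane rank check uses a 1e-10
   tolerance on the centred coordinates).
2. **Visibility graph.** Sensors and markers are nodes of a bipartite graph
   with an edge per sighting. If the graph is connected, every sensor
   reaches the origin marker through shared sightings; if not, calibration
   aborts naming every unreachable sensor. The connectivity decision is
   tested against an independent transitive-closure oracle.
3. **Shortest-path chaining.** Each sensor's pose is the concatenation of
   per-edge transforms along its shortest (unweighted, breadth-first) path
   to the origin. Shorter chains are preferred because each fitted edge
   contributes estimation error; the acceptance suite verifies that median
   pose error in fact grows with path length. Ties are broken by ascending
   node identifier so results are reproducible run to run.
4. **ICP refinement (optional).** Point-to-point iterative closest point
   alignment over per-sensor point clouds, sensors visited in ascending
   path-length order; the sensor nearest the origin anchors the frame and
   never moves, later sensors align against the merged already-fixed
   clouds. Correspondences beyond `max_pair_distance` (0.10 m) or beyond
   three times the current median distance are rejected — the adaptive trim
   lets non-overlap regions fall away as the fit tightens. The source cloud
   is subsampled by deterministic striding (20 %); the fixed target keeps
   full density so that true twin points remain available. Convergence on
   plane-dominated scenes is slow along in-plane sliding directions before
   the exact-correspondence basin is reached, hence the generous default of
   200 iterations with a 1e-7 m tolerance on the capped mean pair distance.
   A sensor with fewer than `min_pairs` (50) close correspondences keeps its
   chained pose, with a warning.

## Skeleton fusion

Streams arrive at "about 30 Hz" on per-sensor clocks, so temporal alignment
precedes averaging:

* **Resampling** to a fixed-rate grid (30 Hz default) by linear
  interpolation. A grid sample is valid only when both flanking raw frames
  are *tracked* and at most `max_gap` = 0.2 s apart (about six frames);
  inferred joints are deliberately distrusted and treated as missing, since
  a fitter's guess for an occluded joint is exactly the data one does not
  want in a validation study. The grid for a multi-sensor recording starts
  at the latest stream start (intersection of time ranges).
* **Averaging** with equal weights across sensors with a valid sample —
  nothing is known about per-sensor noise levels, so no weighting scheme is
  defensible. The contributing-sensor count is recorded per sample.
* **Smoothing** with a zero-phase low-pass Butterworth filter, order 4,
  cutoff 6 Hz. No specific filter is canonical for this step; this is a
  conventional gait-analysis choice (gait-band content lives well below
  6 Hz at a 30 Hz rate). The filter runs forward and backward over each
  contiguous valid segment with odd-reflection end padding (the plain
  forward–backward pass has edge transients otherwise); segments shorter
  than three times the filter's effective length pass through unfiltered,
  and the validity mask is never altered. The tests check the measured
  amplitude response against the analytic bilinear-transform magnitude
  (< 1 % attenuation at 1 Hz, > 95 % at 14 Hz).

## Gait parameters from ankle crossings

Walking direction is not assumed known: the forward axis is the unit
horizontal direction of the net mid-ankle displacement (at least 1 m of
travel required), the lateral axis is vertical × forward. All parameters are
invariant under global rigid motions of the scene, which is tested.

Foot events are the zero crossings of *d(t)* = left − right forward ankle
position, with sub-sample timing by linear interpolation. A crossing is
accepted only after |*d*| has exceeded a hysteresis (0.02 m default) since
the previous accepted event; this suppresses chatter when noise wiggles *d*
around zero, and the rule is tested against a brute-force enumeration
oracle. The passing foot is the one moving faster (central differences); the
other is in stance.

The placement scheme is the package's single largest interpretive decision:
at a crossing the stance ankle's forward position is a plateau equal to
where the foot was placed, so each placement is read as *the stance ankle's
projected position at the crossing time*. The decision is isolated in
`extract_placements()` so alternatives (e.g. a plateau-median position)
could be swapped without touching anything else. Consecutive placements must
alternate feet; a repeated stance foot drops the weaker event (smaller
crossing slope) and flags the recording.

From placements *p*₁…*p*ₙ: step *k* belongs to the foot of *p*ₖ (the foot
last placed); step length = forward advance (cm), step width = unsigned
lateral separation of consecutive placements (cm), step time = elapsed time
(s); stride length = forward distance between consecutive same-foot
placements (cm); walking speed = Σ step length / Σ step time (cm/s), an
identity the tests assert exactly. Because the first step after gait
initiation is atypical, the first step of the starting foot (left by
convention) and the first stride of the opposite foot are excluded from all
outputs. Step width between consecutive placements — rather than between
simultaneous foot positions at the placement instant — is the chosen
reading of an ambiguous definition; the two differ only by lateral sway
within half a gait cycle.

Reference-system trajectories (e.g. 120 Hz optical marker data) run through
the *identical* procedure after resampling onto the same 30 Hz grid and the
same filter, so method differences cannot masquerade as system differences.

## Agreement statistics

Paired values are formed per recording, foot and parameter: by chronological
rank when both systems report the same count, otherwise by greedy
nearest-event-time matching within 0.2 s (gait events are ~0.6 s apart, so
the greedy match is the optimal one in practice — tested against exhaustive
matching on step-like times). Dropped values are counted, never silently
discarded.

For differences *d* = A − B:

* bias = mean(*d*) — exactly mean(A) − mean(B), an identity used as a
  cross-check on published summary rows;
* RPC = 1.96 · sd(*d*) (sample sd). Source descriptions of the RPC conflict
  (sd versus 1.96·sd); the printed RPC/CV ratios of the stride-length row we
  use as a consistency fixture are only reproducible with the 1.96 factor,
  so that is implemented, with the raw sd also returned;
* CV = 100 · sd(*d*) / grand mean of the pairwise means (A+B)/2. The
  alternative "sd of mean values" reading is inconsistent with the same
  fixture row and is not used;
* ICC(A,1), the two-way absolute-agreement single-measure intraclass
  correlation, computed from the two-way ANOVA mean squares
  (MS rows/columns/error); equality with an independent `aov()`-based
  oracle to 1e-10 is part of the acceptance suite. At the single-step level
  each step is a row; at the subject levels, subjects are rows of averaged
  values. Categories poor/fair/good/excellent are half-open intervals
  [0, 0.4), [0.4, 0.6), [0.6, 0.75), [0.75, 1] — the printed ranges leave
  gaps between 0.59/0.6 and 0.74/0.75, which half-open intervals close
  without moving any printed value across a boundary. Negative ICCs are
  classified poor.

## The synthetic-data generator

The generator's role is to supply every pipeline input with exact ground
truth:

* **Rig**: paired left/right sensors per row; defaults 3 rows, 2.5 m row
  spacing, 2 m across, 35° inward rotation, 70°×60° field of view,
  0.5–4.5 m depth range, 0.8 m mounting height. At these defaults the union
  of the frusta covers ~9–10 m of corridor at torso height with ~2 m of
  overlap between consecutive rows, and floor markers placed every 2.5 m
  from x = 1.5 m are each visible to the one or two nearest rows — giving a
  connected visibility graph whose chains reach five edges, which is what
  makes the error-growth property observable.
* **Walker**: each ankle's forward position is exactly constant during
  stance and advances one stride length along a raised cosine during swing
  (C¹ at the boundaries; no particular functional form is canonical, the
  raised cosine is the simplest smooth one). Defaults: step length 0.73 m,
  step width 0.12 m, cadence 100 steps/min, duty factor 0.6 (duty ≤ 0.5
  would abolish double support and is rejected). The left foot swings first
  from a mid-gait posture, so the first detected placement is the right
  foot. Crossing times and placement positions follow in closed form, and
  the emitted ground-truth step table satisfies the walking-speed identity
  exactly. The remaining 21 joints are kinematically slaved to the ankles
  (pelvis mid-feet, trunk and arms at fixed offsets) — adequate because the
  pipeline consumes ankle trajectories only.
* **Corruption**: per-sensor jittered clocks (±2 ms, matching
  hardware-synchronised rigs; ±0.5 Hz rate wobble), isotropic joint noise,
  frustum culling, self-occlusion dropout (a far-leg joint whose line of
  sight passes within 0.08 m of the near-leg hip–ankle segment is reported
  untracked; left-placed sensors therefore only ever drop right-leg joints,
  which is tested), and a lateral surface-pull bias: every joint is
  displaced by `lateral_bias` along the cross-walk axis toward the sensor's
  side, modelling joint estimates that sit closer to the surface each
  sensor actually sees. The displacement is applied laterally rather than
  along the full joint-to-sensor direction so that the injected magnitude
  *b* is exactly the lateral offset a one-sided reconstruction inherits —
  and exactly what symmetric two-sided averaging cancels.

What the simulator does **not** emulate: the real skeleton-fitter's failure
modes. Real pose estimators produce correlated, pose-dependent,
occasionally catastrophic joint errors; the simulator's noise is white and
its occlusion rule is a clean geometric proxy. Two consequences matter for
interpreting green tests. First, passing recovery bounds here show the
*pipeline* is unbiased and correctly assembled, not that any physical
sensor meets those bounds. Second, the published one-sided step-width
degradation is driven by the fitter mislocating a half-occluded far leg; a
mirrored surface-pull bias alone cannot reproduce it, because both ankles
of a step shift by the same lateral amount and step width is their
difference. In this simulator the one-sided-versus-two-sided width
difference therefore appears through precision (noise averaging over more
sensors, fewer occlusion gaps — smaller RPC, higher ICC for two-sided
reconstruction), while the bias mechanism is demonstrated on lateral
positions, where two-sided fusion cancels it to well under a tenth of the
injected magnitude. Combining the surface bias *with* occlusion dropout
actually inverts the width comparison (each ankle is then seen mostly by
its own side, inflating two-sided widths by about 2*b*) — a caution against
treating the corruption switches as independently additive.

## Numerical choices and degenerate inputs

* Rotations are validated to 1e-6 orthonormality on construction; pose
  errors are reported as geodesic rotation angle and translation norm. The
  angle metric bottoms out near √machine-ε (~1e-8 rad).
* Exact zeros of the crossing signal on grid points are absorbed into the
  preceding sign so a touch never double-counts.
* Resampling uses the `x₀ + w(x₁−x₀)` interpolation form, which preserves
  constant signals bit-exactly; a grid time coinciding with a raw frame (to
  1e-9 s) is valid on that single tracked frame.
* A zero grand mean flags the CV as undefined (NaN) rather than returning
  an arbitrary number; zero total variance does the same for the ICC.
* Calibration, fusion and the simulator are deterministic given their
  seeds; dataset files are byte-reproducible, which the tests assert.

## Problem sizes

The test and acceptance suites run end to end on one CPU in a few minutes,
using a 6-sensor rig, walks of 6–8 strides, 50 calibration replicates at
5 mm corner noise, 20 noisy gait recordings at 1 cm joint noise, 5-recording
agreement comparisons, 30 ICC oracle datasets, and ICP clouds of a few
thousand points (the nearest-neighbour search is brute force, so cloud
density is the main cost driver). These sizes were chosen so every
statistical assertion has comfortable margin while the whole suite stays
interactive.

## Known limitations

* Straight walks only; turning gait, treadmills and multi-person scenes are
  out of scope, as are heel-strike/toe-off events from vertical kinematics
  and joint angles.
* The placement scheme reads positions at crossings; pathological gait with
  non-stationary stance ankles would bias it (the operation is isolated for
  exactly this reason).
* ICP is point-to-point with brute-force correspondence; very large clouds
  need subsampling, and scenes without structure perpendicular to a
  direction leave that direction weakly constrained.
* The agreement module implements the standard single-level statistics;
  repeated-measures corrections and mixed-effects agreement models are not
  included.
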