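---
title: "Models and methods in mocapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mocapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mocapkit)
```

mocapkit implements the computational stack of an optical motion-capture
pipeline: multi-camera 3D reconstruction with uncertainty statistics,
skeletal feature extraction, unsupervised frame embedding, motion-graph
transition synthesis, and waveform-agreement analysis. This vignette
records the models, the assumptions behind them, the tunable parameters
that matter, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. Skeletons, motion files and conventions

A skeleton is an ordered joint tree: each joint has a parent (the first
joint is the unique root), a 3-vector offset from that parent, an
intrinsic Euler rotation order (e.g. "ZXY"), and a set of free rotation
axes. A motion sequence is an F × C channel table: three root
translation channels followed by one column per free rotation axis, in
skeleton order. Angles are stored in **degrees** end to end — both
supported file dialects (BVH, and the CMU ASF/AMC dialect) write
degrees — and converted to radians only inside the kinematics. The
joint order is fixed at file order; every downstream feature vector
(including the 96-dim point cloud) inherits it, which makes feature
layouts reproducible across runs.

BVH round trips are exact to 1e-6 per channel (motion lines are written
with 10 significant digits, sufficient for channel magnitudes up to
1e4). The ASF/AMC reader is deliberately limited to the CMU dialect
(degree units, `dof rx ry rz` lines); bone-local axis orientations,
joint limits and documentation blocks are parsed but not applied,
because the data model is a plain offset hierarchy. Angle channels
survive conversion to BVH exactly; absolute world poses of ASF files
with nonzero bone axes would differ from a full ASF interpreter, which
is acceptable here because every downstream feature is root-relative.

Forward kinematics follows the BVH convention: a joint's world position
is its parent's position plus the parent chain's rotation applied to
the joint offset; the joint's own rotation only affects its children.
Rotations compose intrinsically in each joint's declared order in a
right-handed frame. The generators use Y as the vertical axis (the BVH
convention).

## 2. Pose features

Per frame the package computes root-relative joint positions (reference
point: the root joint by default, or the joint centroid as a
center-of-gravity proxy), instantaneous angular velocities, and the
96-dimensional point cloud: the first 32 joints in skeleton order
(zero-padded when fewer), flattened as three channels — all x, all y,
all z.

Angular velocity is the first difference at a configurable frame
interval (default 1), divided by the time step. Differences of rotation
channels are wrapped into (−180°, 180°] first, so a 359° → 1° step
reads as +2°, not −358°. The wrap makes velocity nonlinear for steps
beyond a half turn per interval; at realistic frame rates this never
binds.

The five-part body partition (trunk, left/right upper/lower limb) is
assigned by case-insensitive substring rules on joint names, with CMU
and Helen Hayes-style lower-limb names covered by the defaults and an
explicit trunk fallback, so the partition is always total.

## 3. DLT reconstruction and uncertainty

The camera model is the 11-parameter direct linear transformation with
the "+1" denominator normalization, plus radial (k1, k2) and tangential
(p1, p2) distortion evaluated at the undistorted projection in
pixel-normalized coordinates about the principal point. The
normalization scale is width/2; distortion coefficients are therefore
dimensionless and transferable across image sizes. The distortion
displacement is *added* to the ideal projection when simulating, and
inverted by fixed-point iteration (25 iterations) when triangulating.

Calibration solves the rearranged projection equations as a linear
least-squares problem (two rows per control point); at least 6
non-coplanar points are required and a design-matrix rank below 11
raises an error rather than returning a degenerate camera.

Triangulation first solves the linear rearrangement across cameras,
then polishes the point with a quasi-Newton minimization of the
uncertainty ε = (1/c) Σ (δU² + δV²); the polish is kept only if it does
not increase ε. The residual-balance conditions (camera sums of δU and
δV vanish) are treated as *optimality conditions* of this unweighted
least-squares problem — they are verified on symmetric rigs in the
tests — not as constraints imposed during solving. Whether uncertainty
is minimized per point or jointly per frame was an open question;
per-(frame, marker) minimization was chosen as the only variant whose
statistics decompose exactly into the ε_a / ε_b identities.

The two-step distortion refinement alternates (1) refitting L on
control points observed in the central 50% × 50% image box (the
low-distortion region; the fraction is a config knob) after removing
the current distortion estimate from the observations, and (2) a linear
least-squares fit of (k1, k2, p1, p2) on all points holding L fixed —
linear because the distortion displacement is linear in the
coefficients once the ideal projections are fixed. The all-point
reprojection RMS is tracked; a step that would raise it is rolled back
and iteration stops, so the reported trace is non-increasing by
construction.

## 4. The ConvRBM embedding

The paper-level description names an RBM/ConvRBM but prints no
equations, so the standard Gaussian-visible, Bernoulli-hidden
convolutional form was adopted: visible units form a C-channel ×
32-position array, K filters of width w slide along the position axis
in valid mode (H = 32 − w + 1 hidden positions per filter), and

E(v, h) = Σ (v − b_vis)²/2 − Σ_k Σ_p h_kp (b_k + (W_k ⋆ v)_p).

A `binary01` visible type restricts states to {0, 1} under the same
energy; it exists so that tiny models are *exactly enumerable* — the
test suite brute-forces the partition function over all 2^(nv+nh)
states and checks the implementation's free-energy-based likelihood to
1e-10. Training is CD-k (default k = 1, mini-batch 32, learning rate
1e-3, no momentum), deterministic given a seed; reconstruction uses the
Gaussian mean field rather than sampling, the usual stabilization.
Learning rates much above 1e-2 diverge on Gaussian visibles (weights
grow without bound); the divergence is detected and reported with the
epoch rather than silently propagating NaNs.

Embedding: per frame, hidden conditional probabilities are max-pooled
over positions per filter, giving D = K dimensions (probabilistic
max-pooling simplified to deterministic max-pooling at encode time).
The optional autoregressive history (order m) adds linear shifts to the
visible and hidden biases; m = 0 reduces exactly to the plain RBM — an
identity the tests assert.

**Input mode.** The embedding's input slab is configurable:
`"positions"` is the 3-channel point cloud; `"dynamics"` (the pipeline
default) appends the point cloud's first temporal difference as three
more channels. The reason is a property of the synthetic world that
generalizes to cyclic motion: both styles are zero-mean oscillations,
so single-pose geometry barely separates them (a nearest-centroid
classifier on raw standardized point clouds is near chance), while
frame-to-frame displacement separates them almost perfectly — style
lives in dynamics. This mirrors the pipeline's own use of instantaneous
angular velocity as a first-class feature. With the dynamics mode the
style-separability smoke property (nearest-centroid accuracy ≥ 90% in
embedding space) holds with margin; with positions only it plateaus
around 85% in this world.

**Standardization.** Features are standardized with statistics computed
on the *pooled* training data (`feature_stats`), passed explicitly to
`encode`. Standardizing each sequence by its own statistics — the
obvious default — silently removes the between-sequence amplitude
differences that carry style, and measurably destroys separability;
this is called out in the documentation because it is an easy mistake
for users to reproduce.

Similar-frame detection is a brute-force Euclidean scan (the F² cost is
trivial at motion-capture scales): all pairs under a threshold, sorted
by distance, with self-matches excluded inside a temporal exclusion
window. The default threshold is the 15th percentile of the pairwise
distance distribution — the contract says only "preset threshold", so
the default is data-driven and explicit in the config.

## 5. Motion graph and transition synthesis

Nodes group frames of *one* sequence connected by candidate pairs
(connected components; isolated frames are singleton nodes); temporal
edges chain consecutive frames with similarity 1; each candidate pair
adds transition edges in both directions with similarity
1/(1 + distance), mapping distance 0 to similarity 1 monotonically.
Grouping across sequences was rejected: a merged cross-sequence node
would let a path change sequences without crossing any transition edge,
making the "choose the highest-similarity transition" rule vacuous.

Path selection maximizes the bottleneck (minimum) similarity over the
path's transition edges, extending the stated rule for parallel edges
to multi-edge paths; ties break toward fewer transition edges, then the
earliest source frame, making selection deterministic. The
implementation thresholds the edge set and checks reachability
(igraph); the tests verify it against an exhaustive simple-path
enumeration on small graphs.

Blending uses a linear window of W frames (default 30): weight
w_i = i/(W − 1), root translation interpolated linearly, joint
rotations blended by quaternion slerp in each joint's Euler order
(joints with fewer than three free axes fall back to per-channel
shortest-arc interpolation, since an arbitrary blended rotation need
not stay in their channel subspace). The first and last blend frames
equal the source and target frames exactly, by construction.

**Root alignment.** Two stated properties collide when styles travel at
different speeds: (a) the spliced output should end exactly on the
target's absolute trajectory, and (b) the output's frame-to-frame root
displacement should never exceed the inputs'. Blending absolute root
positions satisfies (a) but injects a catch-up drift violating (b)
whenever the matched frames sit at different absolute positions — with
walking at 1.2 m/s and running at 3.5 m/s the overshoot is roughly 60%
over a 30-frame window. `synthesize` therefore exposes
`root_align = "velocity"` (default): the blend interpolates the two
streams' root *velocities* and integrates, and all downstream frames
are rigidly translated to continue the integrated trajectory. Every
output step is then a convex combination of input steps, so the
continuity bound holds identically; since motion is
translation-invariant, the rigid offset is immaterial. The literal
absolute-coordinate behavior remains available as
`root_align = "none"`, and rotation channels are identical under both
modes. The blend window is fixed (default 30); an adaptive "calculated
transition length" was mentioned but never specified, so the window is
a config override instead.

## 6. CMC waveform agreement

The coefficient of multiple correlation is computed in the within-day
Kadaba form: the ratio of the across-curve variance at each time sample
to the total variance, subtracted from one, under a square root. Curves
are time-normalized to 101 samples per cycle (the standard 0–100% gait
grid, configurable) by linear interpolation. Mean-shift alignment
translates each of system A's trials so its mean equals system B's
grand mean — a vertical shift only, leaving shape and variance
untouched. When the variance ratio exceeds 1 (curves disagree more than
the waveform varies) the CMC is undefined; it is reported as an
explicit flag with a reason rather than clamped to zero, preserving the
diagnostic meaning. Trial counts are not restricted beyond M ≥ 2; the
per-(joint, plane) report lists unmatched joints as skipped rather than
failing.

## 7. The synthetic world

The generators define the package's stated world; they emulate, not
reproduce, the data a motion-capture stage would deliver:

* **Skeleton**: a 32-joint humanoid template (trunk chain + four limb
  chains) with CMU/Helen Hayes-style names, offsets in meters jittered
  slightly by seed. 32 joints exactly fill the 96-dim point cloud.
* **Styled motion**: per-channel sinusoids, amplitude and phase drawn
  deterministically from the style name, plus Gaussian angle noise
  (default 0.5°). Walking: 1 Hz, 25° base amplitude, 1.2 m/s; running:
  2.5 Hz, 45°, 3.5 m/s; jumping: 0.9 Hz, 35°, 0.3 m/s with a 0.30 m
  vertical bounce. Frequencies and amplitudes are ordinary human gait
  magnitudes, set once; styles are separable in frequency–amplitude
  space yet overlap enough in pose space to exercise thresholds.
* **Camera rig**: n cameras (default 8, the usual stage count) evenly
  spaced with angular jitter on a 3.5 m circle at 1.6 m height, looking
  at the volume center; 1200 px focal length, 1280 × 1024 image. DLT
  parameters are derived from the pinhole pose, and the tests verify
  the derived projection against an independent rotation-matrix pinhole
  oracle. Known distortion can be injected for recovery experiments.
* **Observations**: projected markers plus i.i.d. Gaussian pixel noise;
  degenerate projections are excluded with a count. Under noise σ the
  expected per-point ε is 2σ², which the tests verify by simulation.
* **Two-system waveforms**: trials are signal + offset + noise (system
  A) and signal + noise (system B); the closed-form expected CMC
  sqrt(1 − σ̄²/(var(signal) + σ̄²)) is first-order in the noise/signal
  variance ratio and is used as the recovery target at ±0.05.

What a green test does **not** establish: the sinusoidal styles have no
gait events, no soft-tissue artifact, no marker occlusion or mislabeling,
noise is Gaussian and independent across channels, and the two-system
generator has no time-warp between systems — only a vertical offset. The
measured agreement numbers of any real optical-vs-inertial comparison
depend on hardware and subjects and are out of scope by design.

## 8. Numerical choices and degenerate inputs

* Projection denominators below 1e-12 raise a degeneracy error.
* Triangulation condition numbers above 1e10 attach an
  ill-conditioning flag instead of failing.
* Quaternion extraction near gimbal lock (|cos b| < 1e-9) sets the
  third angle to zero and absorbs the remainder into the first.
* Slerp falls back to normalized lerp within 1e-10 of parallelism, and
  sign-flips for the shortest arc.
* The refinement and triangulation polish never accept a step that
  worsens their objective, so their traces are monotone by
  construction, not by hope.
* CMC returns a flagged NA on zero total variance.
* Serialization uses JSON/CSV with full numeric precision (one ulp of
  round-off is tolerated in tests); no binary formats anywhere.

## 9. Known limitations

Inverse kinematics, marker-to-skeleton solving, C3D/FBX, multi-layer
deep-belief stacking, GPU training, online trajectory-following
control, foot-skate cleanup, and gait-event detection are out of scope.
The ASF reader ignores bone-local axis frames (see §1). The CRBM
history terms are linear bias shifts, deliberately the simplest
conditioning consistent with "autoregressive model on the input layer".
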