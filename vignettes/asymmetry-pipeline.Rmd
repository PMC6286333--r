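---
title: "Back-surface asymmetry analysis: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-surface asymmetry analysis: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backsym)
```

## The screening problem

Idiopathic scoliosis is a three-dimensional spinal deformity whose clinical
severity standard, the Cobb angle, requires a radiograph. Screening aims to
decide — without radiation and without an expert — whether a child's back is
asymmetric enough to warrant an x-ray. In the Adams forward-bending pose the
paraspinal rib hump caused by vertebral rotation becomes visible on the back
surface, so a single depth-sensor frame of the bent back carries the signal.

`backsym` quantifies that signal as a scalar **asymmetry index**: the back
surface is reflected across its approximate median sagittal plane, the
reflection is rigidly re-fitted to the original surface, and the index is the
mean residual point-to-plane deviation (mm) between surface and fitted mirror
image over a regular grid,

$$ I_{asym} = \frac{1}{|G_v|} \sum_{(l,m) \in G_v} d_{l,m}. $$

A perfectly mirror-symmetric back gives $I_{asym} = 0$; the index grows with
the deformity. Because the mirror fit is re-estimated by registration, the
index is insensitive to how the subject happened to stand relative to the
sensor — the property that makes the method marker-free and automatic.

## Coordinate convention

The sensor sits at the origin with **+z pointing into the scene** (depth
increases with z). After pose normalization **+x is craniocaudal** (breech at
lower x) and **+y mediolateral**, so the approximate median sagittal plane is
the x–z plane. All lengths are millimetres.

## Pipeline stages

1. **Smoothing** (`smooth_cloud`): each point is replaced by the centroid of
   its 5 mm neighborhood. The window is a radius-based moving average, single
   pass; 5 mm is 2–4× the point spacing of a consumer structured-light sensor
   at the working distance, enough to suppress depth noise without flattening
   a centimetre-scale hump.
2. **Segmentation** (`segment_regions`, `select_body_region`): smoothness-
   constrained region growing over a 10-nearest-neighbor graph. Seeds are
   taken in ascending order of PCA surface variation; a neighbor joins when
   the angle between its normal and the normal of the point it was reached
   from is below 10°. We compare neighbor-to-neighbor (not neighbor-to-seed)
   normals: a smooth hemisphere should stay one region even though its total
   normal variation far exceeds the threshold. The body is the region closest
   to the sensor (minimal mean z) whose bounding-box side-length sum exceeds
   650 mm — a gate that admits a torso and rejects furniture-scale clutter
   while the floor, although large, loses on depth.
3. **Pose normalization** (`pose_normalize`): PCA of the body region;
   largest-variance axis to x, second to y, third to z, centroid to origin.
   PCA signs are arbitrary, so they are fixed deterministically: +z keeps the
   scene-depth direction, +x puts the wider (breech) end of the width profile
   at lower x, and y completes a right-handed frame. Any deterministic rule
   would do — the mirror fit re-estimates pose — but this one keeps the
   cranial/caudal semantics of stage 4 stable.
4. **Back boundaries** (`project_to_binary`, `width_function`,
   `fit_width_polynomial`, `find_back_boundaries`, `crop_back`): the cloud is
   projected to a 3 mm binary occupancy image, the per-column black-pixel
   width is fitted with a 10th-order polynomial (on an abscissa normalized to
   $[-1, 1]$; a raw 10th-order Vandermonde on mm abscissas is numerically
   hostile), and the neck and breech boundaries are the width minima: the
   smallest-valued interior minimum in the cranial 40% of the x-range (neck)
   and in the caudal 30% (breech). The windows come from forward-bend
   anthropometry — the neck dip sits above mid-back, the waist dip below —
   and fall back to the domain ends with a warning when a window has no
   interior minimum. The crop is in x only over the full y range.
5. **Reflection and width restriction** (`reflect_sagittal`,
   `restrict_width`): mirror about the x–z plane; both clouds are then
   restricted to the central 90% of their y-extent because the outer bands
   are seen at high incident angle and carry the largest sensor error.
6. **Mirror registration** (`best_fit_with_perturbations`,
   `icp_point_to_plane`): point-to-plane ICP fits the reflected cloud to the
   original. The original surface is the fixed side (it provides the tangent
   planes); pairs whose normals disagree by more than 50° are discarded
   (gate applied in the current iterate's pose); there is no distance gate by
   default (one is available in `icp_config`). Each start runs exactly 50
   iterations of the standard small-angle 6-DOF linearization. Because the
   converged fit depends slightly on the initial orientation, the ICP is
   restarted from a 9 × 9 grid of ±5° pre-rotations (1.25° steps) about x
   and y and the start with the smallest mean squared point-to-plane
   distance wins; ties break toward the lowest grid index and restarts are
   pure, so any evaluation order gives the identical result.
7. **Colormap deviations** (`colormap_deviations`): for rendering only, the
   fitted mirror cloud is triangulated (Delaunay over the xy projection;
   triangles with an edge beyond 4× the median point spacing are dropped so
   holes are not bridged) and each original point casts a ray along its
   normal; hits beyond 100 mm are ignored. These distances never enter the
   index.
8. **Grid resampling and the index** (`align_union_axes`,
   `resample_on_grid`, `effective_and_valid_sets`, `grid_deviations`,
   `asymmetry_index`): both clouds are re-aligned on the principal axes of
   their union (axis signs chosen nearest to the incoming axes — the
   breech-based rule of stage 3 has no meaning after the crop), then
   resampled at the nodes of a 3 mm grid. The local surface at a node is the
   sphere through the nearest (in xy) cloud point with that point's PCA
   normal and least-squares-sphere radius of curvature — a plane when the
   point is planar-flagged — intersected with the vertical line through the
   node, keeping the intersection nearer the through-point. A node is
   *effective* when its nearest projected point lies within
   $\sqrt{\Delta x^2 + \Delta y^2}$ and both clouds resample there; within
   each column the *valid* set keeps the central fraction $\alpha$ of the
   effective m-range (the printed per-column inequality), trimming the
   high-incident-angle boundary. Deviations are unsigned point-to-plane
   distances using normals re-estimated by PCA over the resampled 25 mm
   neighborhood, and the index is their exact mean. The operating point is
   $\alpha = 0.9$.

### Curvature estimation

The registration and resampling stages need a per-point radius of curvature.
PCA gives the normal (smallest-eigenvalue eigenvector of the 25 mm
neighborhood covariance, re-oriented to face the sensor); the radius comes
from an algebraic least-squares sphere through the same neighborhood. When
the sphere improves the plane-fit RMS residual by less than 1%, the fitted
radius exceeds $10^4$ mm, or fewer than 5 neighbors exist, the point is
flagged planar and its patch degenerates to the tangent plane. The side of
the surface on which the sphere centre lies is kept per point so the patch
is reconstructed on the correct side.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| smoothing window | 5 | mm | moving-average radius |
| region-growing angle | 10 | deg | smoothness constraint |
| body-size gate | 650 | mm | bbox side-length sum |
| projection pixels | 3 | mm | stage-4 image resolution |
| width polynomial order | 10 | — | boundary detection |
| width restriction | 0.90 | — | central y fraction registered |
| normal gate | 50 | deg | ICP pair validity |
| restart grid | ±5 / 1.25 | deg | ICP initial rotations (x, y) |
| iterations per start | 50 | — | fixed, no early stop |
| r5, r8 | 25 | mm | normal/curvature neighborhoods |
| colormap gate | 100 | mm | stage-7 distance cut |
| grid spacing | 3 | mm | stage-8 resampling |
| alpha | 0.9 | — | valid-band fraction per column |
| posture gate | 7.5 / 15 | deg | capture validity (x / y tilt) |

All of these surface in `run_config()` and round-trip through a JSON config
file.

## The synthetic torso generator

No deposited scans exist, so `torso_spec()`/`generate_scan()` emulate what
the sensor captures: a smooth convex forward-bend back whose half-width
profile produces the waist and neck minima stage 4 needs, breech and
neck/occiput extensions, a floor plane 400 mm behind the body, additive
Gaussian depth noise (σ = 1 mm consumer-grade, 0.2 mm digitizer-grade), and
a rigid pose perturbation applied last. The deformity is an additive
anisotropic Gaussian hump on one paraspinal side (two opposite-sided humps
for a double curve); its amplitude is a monotone *proxy* for severity, not a
biomechanical model — synthetic severity–index correlations are
construction-dependent and must not be compared numerically to clinical
correlation coefficients. The sampling grid is symmetric in y, so a
zero-amplitude, zero-noise phantom is *exactly* mirror symmetric and the
whole pipeline must return an index near zero on it (our regression bound is
0.05 mm, covering resampling discretization).

What the generator does **not** emulate: clothing and hair artifacts,
sensor-specific systematic depth bias, occlusion-driven holes, arms entering
the frame, and breathing motion. Passing tests on these phantoms therefore
validates the geometry and statistics of the pipeline, not its robustness to
real-world capture artifacts.

## Numerical choices and degenerate inputs

* Exact k-d-tree radius queries (never approximate); the neighbor budget is
  grown until no query saturates.
* The width polynomial is fitted by QR on the normalized abscissa; the ICP
  6-DOF solve falls back to an SVD pseudo-inverse when the normal matrix is
  singular (e.g. a pure plane leaves rotation about the normal free).
* Sphere/vertical-line intersections with negative discriminant mark the
  node ineffective rather than erroring; empty valid sets, empty crops,
  all-gated ICP pairs and degenerate covariances raise errors naming the
  stage.
* Ties: ICP restarts break toward the lowest grid index; the Youden cut-off
  breaks toward the lower threshold (a screening tool prefers sensitivity).
* Boundary grading values (CV exactly 10%, ICC exactly 0.9) fall in the
  worse band, matching the open/half-open printed bands.

## Screening statistics

`roc_with_youden` evaluates the ROC at midpoints between sorted distinct
scores (positive when the index is at or above the cut-off), computes AUC by
the trapezoidal rule — which equals the Mann–Whitney U statistic scaled by
$n_+ n_-$, the identity the tests exploit — and picks the Youden-optimal
cut-off. The AUC confidence interval is DeLong's by default with a seeded
percentile bootstrap as an option; the interval method behind published
intervals is generally unstated, so no numeric matching of intervals is
attempted. `icc_two_way` is the two-way mixed, absolute-agreement,
single-measure ICC (McGraw & Wong), the conventional choice for test–retest
designs; other ICC forms give different values on the same data, which is
why the model is stated prominently. `coefficient_of_variation` and the
grading bands, and the Fisher r-to-z comparison of two correlations, follow
the standard formulas. One worked example deserves a note: recomputing the
Fisher test from rounded published correlations (0.92 vs 0.86 with n = 18
and 58) gives p = 0.31 — the qualitative conclusion (no significant
difference) is reproduced, the third decimal of a p-value computed from
2-digit inputs cannot be.

## Problem sizes used in tests and the acceptance script

The generator's default 2.5 mm pitch reproduces sensor-scale point counts
(≈ 22 000 body points) and is used for the full-pipeline symmetry check.
Multi-run experiments (amplitude monotonicity, ten noisy re-scans, rotation
robustness) use a 5 mm pitch and the 3 × 3 corner restart grid (±5° at 5°
steps): these measure relative changes of the index between runs of the
identical configuration, which the coarser sampling preserves, and they keep
a thirteen-pipeline experiment at desk scale. The full 9 × 9 grid and
default pitch remain the operating defaults of `run_config()`.

## Known limitations

* The hump model is geometric; no claim is made about the mapping from Cobb
  angle to surface shape, so synthetic ROC/correlation figures characterize
  the construction, not clinical performance.
* The stage-4 crop is x-only; arms or hands entering the y range are not
  removed.
* Published clinical figures (AUC 0.96, cut-off 3.28 mm, r = 0.88,
  ICC 0.995) come from a 76-patient cohort and plaster phantoms that are not
  available; the package reproduces the *procedures* and their desk-scale
  properties, not those numbers.
* A single depth frame is assumed; multi-frame fusion and live capture are
  out of scope.
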