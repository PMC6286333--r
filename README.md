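# backsym

Marker-free screening support for idiopathic scoliosis from a single
depth-sensor point cloud of the back in the forward-bending (Adams test)
pose.

Clinically, scoliosis severity is read from radiographs as the Cobb angle;
screening should decide who needs that radiograph without radiation, markers
or an expert. In the forward-bending pose the paraspinal rib hump produced by
vertebral rotation is visible on the back surface, so its left–right
asymmetry carries the screening signal. `backsym` turns one raw scan into a
scalar **asymmetry index**: the back surface is segmented and pose-normalized,
reflected across its approximate median sagittal (x–z) plane, the reflection
is rigidly best-fitted back to the original by perturbation-restarted
point-to-plane ICP,

$$ \min_{R,t}\; \frac{1}{|\{(p_{c(i)}, p_i^r)\}|} \sum_i
   \left| n_{c(i)} \cdot (R p_i^r + t - p_{c(i)}) \right|^2 , $$

and the index is the mean residual point-to-plane deviation over the valid
nodes of a regular 3 mm grid:

$$ I_{asym} = \frac{1}{|G_v|} \sum_{(l,m) \in G_v} d_{l,m} \quad [\mathrm{mm}]. $$

A perfectly symmetric back scores 0; the index grows with the deformity, and
because the mirror plane is re-estimated by registration the result is almost
unaffected by how the subject stood relative to the sensor.

The package implements the full scan-to-index pipeline (smoothing,
smoothness-constrained region-growing segmentation with a 650 mm body-size
gate, PCA pose normalization, width-polynomial neck/breech cropping,
reflection, ICP with a 50° normal gate and a ±5° restart grid, deviation
colormap, spherical-patch grid resampling, valid-band selection with
α = 0.9), a parametric synthetic torso generator with controllable scoliotic
deformity and sensor noise, the capture posture gate (±7.5° / ±15°), and the
screening-statistics layer: ROC/AUC with the Youden cut-off and the standard
discrimination bands, coefficient of variation and two-way mixed
absolute-agreement ICC with their grading bands, and the Fisher r-to-z
comparison of correlations.

## Worked example

```r
library(backsym)

# a synthetic forward-bend torso with a 6 mm paraspinal hump,
# consumer-grade depth noise, and a 5 degree stance rotation
spec <- torso_spec(hump_amplitude = 6, noise_sd = 1, rot_z = 5, pitch = 5)
scan <- generate_scan(spec)
scan
#> <point_cloud P0: 15522 points>

check_posture(scan)
#> <posture_gate: rot_x -0.28 deg (limit 7.5), rot_y 1.46 deg (limit 15.0) — PASS>

cfg <- run_config(icp = icp_config(perturbation_interval = 5))  # 3x3 restarts
res <- run_pipeline(scan, cfg)
res
#> <asymmetry_result: I_asym = 1.347 mm over 12068 valid grid points (25.3 s)>
```

`I_asym = 1.347 mm` is the mean unsigned point-to-plane distance between the
back surface and its best-fitted mirror image over the 12 068 valid grid
nodes; the same phantom without the hump scores ≈ 0 mm, and the index rises
monotonically with hump amplitude (0, 3, 6, 9 mm amplitude → 0, 0.43, 0.81,
1.14 mm noiseless). Per-node deviations for rendering are in
`res$deviations` and `res$colormap`.

Screening evaluation on a cohort of paired (index, Cobb) records:

```r
coh <- generate_cohort(30, seed = 2, config = cfg,
                       spec_template = torso_spec(pitch = 5, noise_sd = 1))
roc_with_youden(coh, cobb_threshold = 25)
#> <roc_result: AUC 0.987 (0.957, 1.000), cut-off 1.13 mm, sens 1.00, spec 0.94 — outstanding discrimination>
```

A command-line wrapper is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "backsym", package = "backsym"))') \
    analyze scan.ply --json result.json --colormap deviations.ply
```

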