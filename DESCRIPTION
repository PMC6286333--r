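Package: backsym
Title: Back-Surface Asymmetry Analysis for Marker-Free Scoliosis Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automated mirror-symmetry analysis of depth-sensor point clouds of
    the human back in the forward-bending (Adams test) pose. Implements the full
    scan-to-index pipeline: moving-average smoothing, smoothness-constrained
    region-growing segmentation with a body-size gate, PCA pose normalization,
    width-profile back-boundary detection, sagittal reflection with
    perturbation-restarted point-to-plane ICP registration, regular-grid
    resampling through local spherical patches, and the scalar asymmetry index
    (mean point-to-plane deviation between the back and its best-fitted mirror
    image). Includes a parametric synthetic torso generator with controllable
    scoliotic deformity and sensor noise, and the screening-statistics layer
    (ROC/AUC with Youden cut-off, coefficient-of-variation and intraclass
    correlation reliability with standard grading bands, Fisher r-to-z
    comparison of correlations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RANN,
    deldir,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
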