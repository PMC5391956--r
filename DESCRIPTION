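Package: gaitrig
Title: Multi-Sensor Markerless Gait Analysis: Rig Calibration, Skeleton
    Fusion and Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale validation of multi-depth-sensor markerless
    gait analysis. Calibrates the extrinsic pose of every sensor in a rig from
    shared planar-marker observations (rigid Procrustes fits chained along the
    shortest path of a sensor-marker visibility graph, with optional iterative
    closest point refinement), fuses per-sensor 25-joint skeleton streams into
    one uniformly resampled, averaged and low-pass filtered skeleton, extracts
    spatiotemporal gait parameters (step length, step width, step time, stride
    length, walking speed) from ankle-trajectory crossings, and summarises the
    agreement between two measurement systems with Pearson correlation,
    Bland-Altman bias/RPC/CV and the two-way absolute-agreement intraclass
    correlation ICC(A,1). A synthetic-data module generates sensor rigs, marker
    observations, point clouds and corrupted multi-sensor skeleton streams of a
    parameterised walker with known ground truth, so the whole pipeline is
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
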