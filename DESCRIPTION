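Package: quadpoisson
Title: Misalignment-Robust Poisson's Ratio Measurement from Four-Marker
    Quadrilaterals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures Poisson's ratio of soft, highly deformable materials
    (hydrogels and similar biomaterials) from optical tracks of four surface
    markers. Marker positions observed through a moving-stage plus camera
    system are fused into global coordinates, the in-plane strain tensor of
    the marker quadrilateral is computed with first-order isoparametric
    (bilinear 4-node) element kinematics, and Poisson's ratio is obtained as
    the negative ratio of minimum to maximum principal strain, which is
    insensitive to misalignment between specimen, loading axis and camera.
    The classical axis-aligned estimator is included as a baseline, together
    with a synthetic-data generator (homogeneous deformations with
    misalignment, rigid motion and coordinate noise, plus rendered marker-spot
    images) for validation without laboratory hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    EBImage,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
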