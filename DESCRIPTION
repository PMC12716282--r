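Package: wingfa
Title: Wing Morphometrics and Fluctuating Asymmetry for Paired Insect Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies wing-venation morphometrics and fluctuating asymmetry
    (FA) of paired insect wings, with damselflies as the motivating system.
    Provides a synthetic wing-pair generator with known ground truth, raster
    segmentation of wing images into membrane cells and vein junctions,
    per-cell and whole-wing geometric descriptors, mirror alignment and
    optimal sister-cell matching with NRMSE and distance-based asymmetry
    variables, landmark-based generalized Procrustes analysis with a
    bilateral-symmetry FA score, spatial asymmetry mapping on a common
    300 x 300 wing frame, and a GLM layer for stressor-effect inference with
    likelihood-ratio tests and predicted percentage changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    clue,
    interp,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car
Config/testthat/edition: 3
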