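Package: neckssm
Title: Statistical Shape Modelling of the Infrarenal Aortic Aneurysm Neck
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds point-distribution statistical shape models (SSM) of the
    infrarenal abdominal aortic aneurysm neck from triangular lumen surface
    meshes, center lumen lines, and renal-artery landmarks. Provides tubular
    parametrization of the neck (ten cross-sectional rings of 36 ray-cast
    contour points around the centerline), longitudinal point correspondence
    and landmark-based alignment, PCA/SVD shape decomposition with mode-shape
    mesh export, and the standard model-quality metrics: compactness,
    leave-one-out generalization, and specificity. Includes a parametric
    synthetic-cohort generator with controllable shape modes (length,
    lateral and anterior deflection, diameter, distal-end deflection) and
    vertex noise, so every pipeline stage can be validated against
    closed-form geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
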