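Package: normaltex
Title: 3D Surface Texture Descriptors for Dense Facial Normal Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of 3D surface micro-texture from dense per-pixel
    surface normal fields, as captured by photometric-stereo or light-stage
    systems, applied to skin condition assessment (wrinkles, pores, acne).
    Provides Riemannian primitives on the unit sphere and the rotation
    group, geodesic smoothing and resampling of normal maps, three
    normal-field texture descriptors (rotation-fields pyramid, local
    orientation patterns, multi-scale azimuthal projection distance),
    2D-to-3D baseline descriptors, a BTF-texton reference method, a
    synthetic skin-patch generator with graded condition severities, and a
    cross-validated classification pipeline with rater-consensus labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    nnet,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
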