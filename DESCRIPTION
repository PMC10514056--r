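Package: slicereg
Title: Anchoring-Vector Registration of Histological Sections to Volumetric Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with QuickNII-style anchoring vectors that place
    2D histological section images into a 3D reference atlas such as the Allen
    Mouse Brain Common Coordinate Framework. Provides the plane geometry and
    cutting-angle math for anchoring vectors, readers and writers for the
    QuickNII XML and JSON alignment dialects, series-level post-processing
    (angle integration across a sectioned block, cutting-index re-spacing from
    filename metadata, and model ensembling), a masked voxel-distance
    registration error metric with multi-rater consensus ground truth and
    leave-one-out operator scoring, virtual sectioning of volumes with a
    deterministic phantom generator and image augmentation for synthetic
    training data, and a coarse-to-fine template-matching section predictor.
    A command-line interface wires the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    RNifti,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
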