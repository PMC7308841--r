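Package: phenocloud
Title: Morphometric Trait Extraction and Evaluation for 3D Plant Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale tools for evaluating structure-from-motion (SfM) plant
    phenotyping pipelines. Reads and writes ASCII point clouds (PLY, XYZ) with
    optional colour, organ-label and normal channels, rescales clouds to metric
    units from reference markers, masks coloured backgrounds in RGB images by
    supervised colour thresholding, and removes outlier points with a k-nearest
    neighbour statistical filter. From organ-segmented clouds it extracts plant
    and branch heights (straight-line Euclidean), basal/half/apical stem
    diameters from ring cross-sections, petiole and branch inclination angles,
    leaf inclination from total-least-squares plane fits, and convex-hull leaf
    areas. Observed-versus-predicted trait tables are scored with the
    coefficient of determination, relative RMSE, AIC, a missing-value weighting
    adjustment and rRMSE accuracy bands. A synthetic plant generator provides
    gravity-aligned, labelled clouds of three canopy archetypes (erect monocot,
    petiolate herb, woody evergreen) with exact ground-truth traits, plus
    degradation operators emulating image-quantity and image-quality factors
    for response-surface experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
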