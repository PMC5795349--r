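Package: phenomap
Title: Image-Based Maize Phenotyping: Segmentation, Trait Extraction,
    Heritability, and Biomass Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for greenhouse high-throughput plant phenotyping imagery.
    Segments plants from RGB images with a green index, from hyperspectral
    cubes with NDVI and a stem/leaf reflectance ratio, and from fluorescence
    images with a red-channel threshold; extracts height, width, and area
    with zoom-aware pixel-to-millimetre calibration; estimates per-day
    broad-sense heritability from sequential ANOVA sums of squares with and
    without greenhouse row-effect adjustment; predicts fresh biomass from
    image-derived features and decomposes prediction error into genotype and
    residual components. A synthetic phantom-plant generator reproduces the
    full experiment layout (10x16 pot grid, 32 genotypes, 5 replicates,
    243-band hyperspectral cubes) so that every stage can be validated
    against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    stats,
    utils,
    jsonlite
Suggests:
    randomForest,
    e1071,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
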