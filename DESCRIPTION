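Package: sepatch
Title: Social-Ecological Patch Mapping and Livelihood Benefit Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies multi-season satellite imagery into social-ecological
    patches with a hybrid decision-tree workflow (spectral bands, NDVI,
    tasseled cap components, elevation, digitized overlays), converts patch
    maps into weighted livelihood-benefit rasters and a composite heat map,
    and assesses map quality with a buffered relative accuracy, a confusion
    matrix and landcover composition summaries. Includes a synthetic-landscape
    generator with known ground truth so the whole pipeline can be validated
    end to end, plus plain-text raster (Esri ASCII grid) and vector (GeoJSON)
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    withr,
    mgcv,
    EBImage,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
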