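Package: greenspill
Title: Greening Trends and Spill-Over Effects Around Tree-Planting Groves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel vegetation-index trend mapping and spatial spill-over
    analysis around tree-planting grove polygons. Builds monthly
    maximum-value composites from dated NDVI raster stacks, removes the
    seasonal cycle against a multi-annual monthly climatology, smooths with
    a 12-month moving average, and maps the Mann-Kendall tau trend per
    pixel. Pixels are classified as grove, successive 30 m neighbour rings,
    or other agricultural land by centroid/buffer rules, and an
    asymptote-anchored categorical regression over the distance rings
    estimates how far elevated greening extends beyond the groves. Includes
    a synthetic-landscape generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
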