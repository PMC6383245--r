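Package: nichebox
Title: Range-Envelope Ecological Suitability Modelling from Presence-Only Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a rectilinear (axis-aligned box) bioclimatic envelope to
    presence-only occurrence records extracted from a stack of co-registered
    environmental raster layers, scores every raster cell by its Euclidean
    distance to the envelope, reclassifies the distance surface into
    suitability classes, and intersects the climate-suitable region with a
    categorical soil-suitability mask via a binary overlay. Includes optional
    principal-component reduction of collinear climate layers, per-layer
    linear standardisation to a common 0-100 scale, factor-range and
    suitable-area reporting, a synthetic-landscape generator with known
    ground truth for validation, and a deterministic end-to-end pipeline
    driven by a plain-text configuration file. Rasters are read and written
    as ESRI ASCII grids with an optional CRS sidecar.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
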