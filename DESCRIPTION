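Package: footprintr
Title: Cumulative Human-Pressure (Human Footprint) Mapping and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes gridded human-pressure data (built environments,
    population density, night-time lights, crop and pasture lands, roads,
    railways and navigable waterways) onto a common 0-10 pressure scale,
    combines the standardized layers under exclusion rules into a 0-50
    cumulative human-footprint raster, and assesses any footprint map
    against plot-level visually interpreted pressure scores using RMSE and
    a threshold-match Cohen's kappa. Includes hydraulic-geometry based
    river navigability from discharge, distance-decay access kernels, a
    deterministic synthetic-landscape generator for end-to-end testing,
    and raster I/O for TIFF and Esri ASCII grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
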