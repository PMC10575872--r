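Package: inundatr
Title: Wetland Inundation Mapping from SWIR Reflectance Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated mapping of wetland surface-water extent from
    short-wave infrared (SWIR) reflectance time series. Builds
    cloud-masked, gap-filled annual median composites from dated scenes,
    classifies each composite into a binary inundation map with a
    composite-specific SWIR threshold derived from permanent wet and dry
    reference regions, aggregates maps into inundation-frequency grids
    and yearly inundated-area series, tests those series for monotonic
    trends with the tie-corrected Mann-Kendall statistic, and validates
    maps against reference points with 2x2 error matrices. Includes a
    synthetic Landsat-like scene generator so the whole pipeline can be
    exercised end to end without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
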