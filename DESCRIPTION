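Package: canopylue
Title: Canopy Chlorophyll, Light Use Efficiency and Midday GPP from
    Hyperspectral and Eddy Covariance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maize-canopy light use efficiency and midday gross
    primary productivity from field hyperspectral reflectance and eddy
    covariance measurements. Converts SPAD readings and leaf area index to
    canopy chlorophyll content, computes chlorophyll-related vegetation
    indices and the red edge position, exhaustively optimises two-band
    vegetation indices over 400-1300 nm against canopy chlorophyll,
    partitions net ecosystem exchange into respiration and gross primary
    productivity with a windowed Lloyd-Taylor temperature response, and
    calibrates a chlorophyll-based light-use-efficiency model
    GPP = PAR x fAPAR_green x alpha x CCC. Includes a synthetic-season
    generator with planted truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
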