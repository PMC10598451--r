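Package: landising
Title: Kinetic Ising Model for Binary Land-Pattern Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and infers binary land-cover pattern change with a
    two-parameter kinetic Ising model. Landscapes are square grids of focus
    (+1) and background (-1) cells evolved by single-flip Glauber dynamics on
    a torus, with an optional noise-suppression term that prevents isolated
    focus cells from appearing inside all-background neighbourhoods. The
    package provides pattern statistics (composition imbalance, lag-one
    texture index, map-comparison accuracy/recall/precision), patch
    extraction with complementary cumulative distributions of patch size and
    area, simulated-annealing ensemble inference of the external-force and
    coupling parameters from observed pattern transitions, response-surface
    mapping, synthetic landscape and time-series generators with known ground
    truth, and raster input/output (Esri ASCII grid, single-band TIFF, PNG
    previews).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    png,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
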