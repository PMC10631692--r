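Package: landsecr
Title: Landscape Ecological Security Assessment from Categorical Land-Use Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for landscape ecological security assessment:
    per-class landscape structure indices (fragmentation, separation, fractal
    dimension) and disturbance/loss indices from categorical land-use rasters,
    fishnet-grid area-weighted ecological risk (ERI), five-grade security
    classification with fixed or Jenks natural breaks, empirical semivariograms
    with spherical/exponential model fitting and ordinary kriging, global and
    local Moran's I (LISA cluster labeling), area-weighted gravity-center
    migration of security grades, and GM(1,1) grey forecasts of future risk.
    Includes a seeded synthetic land-use generator (region growing, epoch
    transitions, Gaussian random fields) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
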