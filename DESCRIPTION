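Package: tgbcover
Title: Tree and Grass Cover Responses to Intra-Seasonal Rainfall Variability in Tropical Grassy Biomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-grid-cell rainfall descriptors (mean annual rainfall,
    Walsh-Lawler seasonality index, wet-season length, wet-season daily rainfall
    frequency and intensity) from daily precipitation series, converts burnt-area
    fractions into average fire intervals, filters grid cells to tropical grassy
    biomes, and models fractional tree and grass cover with binomial-logit
    generalized linear models selected by AIC across three mean-annual-rainfall
    ranges, including a deviance-residual analysis of predictor collinearity. A
    synthetic-data generator emulates the satellite inputs (daily rainfall,
    burnt area, land cover, vegetation cover) so the full analysis is testable
    without remote-sensing downloads.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
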