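Package: forcarb
Title: Forest Carbon Stock Estimation and Economic Valuation from Stand Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates forest vegetation carbon stocks from sub-compartment
    stand inventories using four volume-to-carbon conversion methods for the
    arbor layer (age-stratified and pooled biomass expansion factors, a fixed
    volume conversion coefficient, and linear biomass-volume functions) plus
    mean-biomass area methods for economic forests and shrubland. Includes
    rank-based method comparison (relative errors against the four-method
    mean, exact Wilcoxon signed-rank tests, Spearman rank correlations),
    monetization of carbon stocks under market-mean and optimal carbon-sink
    price schemes, aggregation reports by species, age group, vegetation type
    and functional zone, and a seeded synthetic inventory generator with
    marginal-total calibration for reproducible end-to-end analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
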