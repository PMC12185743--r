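Package: wrackscale
Title: Scale-of-Effect Analysis of Kelp Forest to Beach Subsidies
Version: 0.1.0
Authors@R:
    person("Coastal", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the spatial scale at which offshore giant
    kelp canopy biomass predicts kelp wrack deposition on sandy beaches.
    Implements buffer-based aggregation of gridded canopy biomass around
    alongshore beach segments over a grid of candidate radii, generalized
    least squares regression with ARMA(1,1) correlation of residuals in
    alongshore order, radius selection by model fit (GLS F or OLS r-squared),
    seasonal stratification, and multi-predictor driver models with
    AIC-based candidate selection. Includes a seeded synthetic-coastline
    generator with planted connectivity radius and known coefficients for
    end-to-end parameter-recovery testing, and a command-line pipeline that
    writes a reproducibility manifest.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
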