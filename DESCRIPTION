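Package: allomvar
Title: Model Errors in Tree Biomass Estimates with Recovered Covariance
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating model errors in tree above-ground biomass
    (AGB) predictions when the covariance matrix of the biomass-equation
    parameters was never published.  Substitutes for the missing residual
    variance and parameter covariance matrix are recovered from the reported
    sample size and coefficient of determination together with resamples of
    the explanatory variables (DBH, height) drawn from the inventory
    population targeted for estimation.  Basic, weighted, refitting
    (parametric bootstrap) and robust (sandwich) recovery procedures are
    provided, together with delta-method propagation of the recovered
    statistics to tree-level, species-mean and per-hectare model-error
    variances, Box's M comparison of covariance matrices, a registry of
    published German and Mexican biomass equations, and a seeded synthetic
    inventory generator for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
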