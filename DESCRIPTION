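Package: dasycan
Title: Dasymetric Refinement and Count Models for Canine Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geographic correlation analysis of canine cancer incidence across
    enumeration units, with binary dasymetric refinement of the units to their
    residential-land portion. Provides a seeded synthetic-region generator
    (raster-lattice municipalities, clustered residential land, road networks,
    veterinary practices, dog demographics, zero-inflated overdispersed cancer
    counts), recomputation of density and road-network distance covariates on
    both spatial supports, maximum-likelihood fitting of Poisson, negative
    binomial, zero-inflated Poisson and zero-inflated negative binomial
    regressions with a log offset, and a model-comparison framework based on
    AIC, pairwise relative likelihoods and likelihood-ratio tests, including
    the cross-support (municipal vs refined) contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
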