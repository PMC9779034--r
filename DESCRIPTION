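Package: arealrisk
Title: Small-Area Risk Mapping with Besag-York-Mollie Models and
    Bayesian Exploratory Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Bayesian small-area analysis of areal count data:
    indirect standardization and standardized morbidity ratios (SMR),
    queen/rook contiguity graphs from GeoJSON polygons or edge lists with
    intrinsic conditional autoregressive (ICAR) structure matrices, a
    Bayesian exploratory factor analysis with dedicated loadings in which
    the number of factors and the variable-to-factor allocation are
    sampled jointly, and the Besag-York-Mollie convolution model (Poisson
    likelihood with offset, ICAR spatial effect and unstructured
    heterogeneity) fitted by Metropolis-within-Gibbs. Includes a
    synthetic areal-study generator, Gelman-Rubin and effective sample
    size diagnostics, choropleth GeoJSON export, and an end-to-end
    pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
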