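Package: effigen
Title: Pedigree-Based Genetic Analysis of Nutrient-Efficiency Traits in Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives protein- and phosphorus-efficiency, performance and
    water-holding phenotypes from carcass-scan and feeder records, estimates
    variance components for pedigree animal models by average-information REML
    (univariate and bivariate, with litter effects and missing-trait records),
    computes heritabilities, litter effects and genetic and phenotypic
    correlations with delta-method standard errors, screens fixed-effect
    structures by all-subsets AIC respecting marginality, analyses sensory
    panel scores with a judge/session mixed model and Fisher's LSD separation,
    and generates pedigreed synthetic data with known genetic architecture for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans
Config/testthat/edition: 3
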