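Package: StrigaSieve
Title: Screening Soil Bacterial Taxa Associated with Suppression of Striga Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies soil bacterial taxa associated with suppression of
    Striga hermonthica infection of sorghum from amplicon count tables and
    host root traits. Provides a two-way (soil x Striga) ANOVA trait screen,
    a Bayesian multivariate joint model of CLR-transformed taxa abundances
    and traits with Gibbs sampling of the residual covariance, extraction of
    residual correlations and within-factor treatment contrasts, a
    rank-aggregation scheme that prioritises candidate suppressive taxa, a
    ppm-window mass-matching screen of predicted haustorium-inducing-factor
    degradation products against untargeted metabolomics features, and a
    seeded synthetic-data generator with planted ground truth for validating
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    vegan,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
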