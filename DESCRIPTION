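Package: coregmap
Title: Shared-Component Geostatistical Mapping of Childhood Comorbidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint Bayesian geostatistical analysis of several binary
    childhood health outcomes (acute respiratory infection, diarrhoea and
    stunting) observed in geolocated cluster surveys.  Latent spatial risk
    is modelled by a triangular linear model of coregionalization over
    independent Matern Gaussian random fields under a Bernoulli/logit
    observation model.  The package provides survey-table validation and
    descriptive statistics, a seeded synthetic-survey generator, dense and
    sparse (SPDE/GMRF) Matern field machinery, MCMC posterior inference
    with elliptical slice sampling, predictive model assessment (DIC,
    WAIC, CPO, PIT), and excursion-set exceedance mapping with raster
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
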