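Package: stabsense
Title: Soft Sensing of Raw-Milk Ethanol Stability from Routine Intake Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the ethanol stability of raw milk from fifteen routinely
    measured physicochemical intake indicators, replacing the destructive
    laboratory ethanol test with a data-driven screening model. Provides a
    seeded synthetic milk-cohort generator, an intake data-cleaning workflow,
    explicit (ANOVA F, point-biserial, random-forest importance, logistic
    coefficients) and implicit (autoencoder latent) feature-relevance analyses,
    a constraint-aware tabular denoising-diffusion generator (Gaussian and
    multinomial forward processes with rejection sampling) for augmenting the
    rare ethanol-unstable class, a sequential-attention tabular classifier with
    sparsemax feature masks plus MLP and gradient-boosted-tree baselines, and
    imbalance-aware evaluation across curated, cleaned and production
    prevalence regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
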