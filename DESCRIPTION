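Package: vcanova
Title: Variance-Component ANOVA for Multi-Site Biodiversity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares the importance of species richness and species
    composition for grassland productivity in multi-site biodiversity
    experiments using three related analyses of plot-level aboveground
    annual net primary production: a least-squares multi-stratum ANOVA
    with Type-I sequential sums of squares and an explicit error-term
    map, a REML crossed-random-effects model with likelihood-ratio
    tests and BLUP per-site richness slopes, and a Bayesian multilevel
    model fitted by a purpose-built Gibbs sampler that yields
    finite-population standard-deviation variance components for every
    explanatory term, displayed as a graphical ANOVA.  Includes a
    forward simulator of the hierarchical model on configurable
    multi-site design skeletons for parameter-recovery testing, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
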