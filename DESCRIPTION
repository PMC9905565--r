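Package: springtailMetrics
Title: Trait-Based Density, Biomass, Metabolism and Richness of Soil
    Springtail Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raw soil springtail (Collembola) community samples into
    site-level density, biomass, individual and community metabolism, and
    extrapolated species richness, and scales these metrics to latitudinal
    gradients and gridded global totals with uncertainty. Body masses are
    derived from genus-level body lengths via group-specific allometric
    regressions; individual metabolic rates follow the metabolic theory of
    ecology with Boltzmann-Arrhenius temperature correction from mean annual
    topsoil temperature. Site richness is extrapolated with sample-based
    rarefaction and the incidence-based Chao estimator, with a completeness
    model for pooled sites. A geospatial module trains a cross-validated
    random-forest ensemble, masks environmental extrapolation with convex
    hulls in principal-component space, and quantifies uncertainty with a
    spatially stratified bootstrap. A synthetic-data generator with known
    ground truth makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ranger,
    ape,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
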