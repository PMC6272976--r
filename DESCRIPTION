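Package: fermkin
Title: Screening Designs, Response-Surface Optimization and Fermentation
    Kinetics for Microbial Enzyme Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for optimizing a microbial fermentation
    medium and modelling batch kinetics of enzyme production. Implements
    Plackett-Burman screening with dummy-factor error estimation,
    second-order (Box-Behnken) response-surface fitting with lack-of-fit
    ANOVA and constrained optimization in coded variables, logistic biomass
    growth and Luedeking-Piret product-formation models with two-stage
    nonlinear/linear estimation and Gaden-type classification, polynomial
    meta-models of kinetic parameters over operating conditions, DNS
    enzyme-activity and rotary-viscometer assay arithmetic, and synthetic
    data generators for every stage. Ships the screening and
    response-surface design tables of a kappa-carrageenase production study
    as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
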