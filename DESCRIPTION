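Package: cbvsim
Title: Stochastic Simulation of Competing Biogeochemical Cycle Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coupled eco-evolutionary and biogeochemical stochastic
    simulator for competition between overlapping cycle-biota variants
    (CBVs). Four microbial species carry a reaction-performing genotype
    that interconverts three variants of an idealized essential nutrient
    J; byproducts of two of the reactions feed a climate-like X-cycle
    with a depletable reservoir and bistable feedback which, above a
    threshold, suppresses one species and so closes a feedback loop
    through which cycle variants "compete" by their climatic side
    effects. The package provides the full Euler-Maruyama integrator
    with multi-timescale coupling, seeded replicate sweeps over
    selection, mutation and feedback parameters, correlation analyses
    between suppression and cycle-variant dominance, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
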