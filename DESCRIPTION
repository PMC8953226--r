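Package: famineSRE
Title: Quantitative Physiology and Metabolome Relaxation Analysis of
    Famine Stimulus-Response Experiments in Glucose-Limited Chemostats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for famine stimulus-response experiments
    (SRE) in glucose-limited chemostat cultures of Saccharomyces
    cerevisiae: simulation of extracellular glucose and biomass under
    continuous or intermittent feeding with metabolic-regime
    classification (overflow / limitation / starvation), identification
    and inversion of first-order-plus-delay off-gas sensor dynamics,
    gas-phase mole balancing into volumetric O2/CO2 transfer rates,
    biomass-specific rate and yield estimation with carbon, nitrogen and
    available-electron recovery closure, adenylate energy charge and
    nicotinamide reduction-charge ratios, and classical multidimensional
    scaling of min-max normalized metabolite panels to visualize
    metabolome relaxation trajectories. A seeded synthetic-data
    generator emulates the experimental design (2-min feed-off / 7-min
    feed-on cycles at an average dilution rate of 0.1 per hour) with
    known ground truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
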