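Package: phenoswitch
Title: Memory-Driven Phenotype Switching and Adaptive Chemotherapy Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates populations of drug-sensitive and drug-tolerant tumour
    cells in which the probability that a daughter cell inherits the parental
    phenotype decays with the age of the mother cell at division (phenotypic
    memory). Provides the exact five-dimensional ODE reduction of the
    age-structured transport model, a direct method-of-characteristics solver
    for cross-validation, one-compartment pharmacokinetics with a saturating
    pharmacodynamic effect on the sensitive death rate, population-fitness
    analytics (Malthusian parameter, basic reproduction number, Floquet
    multipliers under periodic dosing), analytic resistance thresholds,
    multi-start least-squares fitting to growth-assay time series, a seeded
    synthetic-assay generator, and periodic and biomarker-gated
    (model-informed) treatment schedulers with tumour-burden comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
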