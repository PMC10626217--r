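Package: fluxpattern
Title: In Silico In Vivo Association Pattern Analysis for
    Microbiome-Metabolome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal-inference toolkit for paired microbiome-metabolome
    cohorts.  Correlates covariate-adjusted species-metabolite association
    statistics measured in vivo with species-flux association statistics
    computed from constraint-based microbial community models, and assesses
    significance of the resulting per-metabolite association patterns by
    flux-shuffling permutation tests.  Ships a structural-equation simulator
    of metabolic host-microbiome systems for validating the causal
    criterion, and a toy-scale community flux-variability engine (joint
    lumen, diet and fecal compartments, abundance-weighted community
    biomass, coupling constraints) so the full pipeline runs without
    external reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
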