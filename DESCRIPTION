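Package: brainflux
Title: Multi-Compartment Brain Genome-Scale Metabolic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modeling of brain energy metabolism across
    neuron, astrocyte, microglia and oligodendrocyte compartments.
    Provides compartmentalized metabolic-model data structures with
    gene-protein-reaction rules and a JSON interchange format,
    expression-driven context-specific model extraction guaranteed to
    preserve a list of metabolic tasks (a task-checked greedy variant of
    tINIT), merging of cell-type models into a multi-compartment brain
    network with intercellular neurotransmitter and metabolite transport,
    flux balance analysis, flux variability analysis and minimization of
    metabolic adjustment (MOMA) with two-stage (LP then QP) optimization,
    perturbation protocols for ketogenic diet, hypoxia and demyelination,
    subsystem activity summaries, reporter-metabolite scoring from
    gene-level p-values, and hypergeometric metabolite-set enrichment.
    Ships a synthetic toy brain generator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
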