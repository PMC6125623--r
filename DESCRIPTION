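Package: carvenet
Title: Top-Down Reconstruction of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Carvenet", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for top-down reconstruction of constraint-based
    genome-scale metabolic models. Starting from a curated, simulation-ready
    universal reaction network, gene-homology evidence is converted into
    per-reaction confidence scores via gene-protein-reaction (GPR) rules, and
    an organism-specific model is carved out by a mixed-integer linear program
    that maximises evidence while enforcing network connectivity and growth.
    Includes universal-model curation utilities (mass balance screening,
    thermodynamic reversibility assignment, blocked-reaction pruning,
    energy-generating-cycle detection, biomass templates), score-weighted
    gap-filling against growth media, ensemble model generation with phenotype
    voting, microbial community model merging with metabolic interaction
    potential (MIP) scoring, and simulation engines (FBA, FVA, phenotype
    arrays, gene essentiality). Models are read and written as SBML (FBC2 and
    legacy COBRA dialects) or a native JSON dialect. Linear and mixed-integer
    programs are solved through a pluggable backend (default: HiGHS via
    SciPy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
    stats,
    utils,
    tools,
    xml2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH for the
    default LP/MILP solver backend.
RoxygenNote: 7.3.3
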