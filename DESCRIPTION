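Package: iriscc
Title: Cell-Type-Specific Ligand-Receptor Interaction Discovery for
    Immunotherapy Resistance
Version: 0.1.0
Authors@R:
    person("IRIS", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers immune-checkpoint-blockade (ICB)
    resistance-associated, cell-type-specific ligand-receptor interactions
    from deconvolved tumor transcriptomics. Implements median-threshold
    activation calling on deconvolved cell-type-specific expression, a
    two-step trainer combining stratified Fisher-exact differential
    activation screening with hill-climbing aggregative feature selection
    under a permutation null, resistance-downregulated/upregulated
    response scores (RDS/RUS) with cut-point classification, a
    single-cell interaction-inference algorithm based on a cell-type
    label-permutation null, a spatial extension segmenting slides into
    ~250 micrometre regions, synthetic-cohort generators with planted
    signal, and a leave-one-cohort-out evaluation harness with a command
    line interface.
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
    Matrix,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
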