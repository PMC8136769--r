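Package: b3affinity
Title: DNA Binding Kinetics and Thermodynamics of Plant B3 Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking in vitro DNA binding kinetics of plant
    B3 transcription-factor domains (ABI3, FUS3, LEC2, VAL1 and their
    beta4-triad mutants) to in vivo transcriptional activity. Implements
    biphasic (two-component exponential) decomposition of biolayer
    interferometry dissociation time courses, constrained global fitting of an
    independent two-site association/dissociation kinetic model across protein
    concentrations, conversion of dissociation constants to standard binding
    free energies with error propagation, clade-specific variant scanning of
    B3 multiple sequence alignments, and regression of in vivo reporter
    activity against binding free energy. Includes seeded synthetic-data
    generators emulating the biosensor protocol, per-seedling qPCR panels and
    toy alignments, so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    withr,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
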