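Package: sdablib
Title: Design, Simulation and Quality Control of Synthetic Single-Domain
    Antibody Libraries
Version: 0.1.0
Authors@R:
    person("Library", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating fully synthetic
    single-domain antibody (VHH/nanobody) libraries: scaffold consensus
    derivation, humanization with hallmark protection, CDR grafting,
    rational per-position CDR diversity design realized through
    trinucleotide codon mixes, in-silico library generation with a defect
    taxonomy (in-frame stop, frameshift, missing region, empty clone),
    sequencing-based quality control (scaffold-anchored read annotation,
    defect classification, diversity statistics, unique-clone collapsing,
    clonal dominance), 1:1 Langmuir single-cycle-kinetics simulation and
    fitting (kon, koff, KD), and small assay statistics (median
    fluorescence knockdown ratio, differential ELISA calling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
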