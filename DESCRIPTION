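Package: cenRNAtools
Title: Classification and Quantification of Centromeric and Pericentromeric Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Strand-aware classification of RNA-seq fragment spans against
    budding-yeast point-centromere annotation (CEN core, CDEI/II/III
    elements, pericentromeric windows and their ORFs), per-nucleotide
    coverage and start-site profiling in CEN-anchored coordinates with CPM
    normalisation, abundance ratio and fold reporting, absolute
    molecules-per-cell calibration against reference genes, delta-delta-Cq
    relative quantification, and a seeded synthetic fragment generator that
    emulates a mock versus auxin-depletion experiment so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
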