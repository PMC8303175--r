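Package: tpsmap
Title: Genome-Wide Mapping of Transcript Processing Sites from dRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcript processing sites (TPS) from paired
    TEX-treated and untreated differential RNA-seq libraries by testing
    per-position read 5'-end counts for exonuclease-mediated depletion
    (TEX- > TEX+) under a windowed-Poisson/Skellam null, clusters
    significant positions into sites, normalizes site positions relative
    to coding sequences, and layers cross-species conservation in
    ortholog pairs, sense/antisense coincidence, growth-phase
    differential processing and ribosome-profiling peak overlap on top.
    Includes a seeded synthetic dRNA-seq generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
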