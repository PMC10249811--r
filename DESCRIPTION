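Package: retroscout
Title: Discovery and Characterization of Gene Retrocopy Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polymorphic gene retrocopies (retroCNVs) from paired-end
    whole-genome sequencing data and characterizes them end to end. Parent
    genes are called from spliced-mRNA-specific k-mers absent from the
    reference genome, insertion sites and target-site duplications are
    resolved from discordant and soft-clipped read alignments, cohort
    variants are attributed to retrocopies versus parent genes, copy number
    of amplified retrocopies is estimated from read depth, retrocopy versus
    parent expression is partitioned on an N-masked transcript, and
    retrotransposition events are dated from sequence divergence under a
    molecular clock. A synthetic-data generator with full ground truth makes
    every stage testable without external aligners or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
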