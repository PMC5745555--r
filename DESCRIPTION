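Package: syntorth
Title: Synteny-Based Orthology and Event Analysis for Multicopy Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers orthology among multicopy genetic elements that evolve
    under concerted evolution, where sequence similarity alone cannot separate
    orthologs from paralogs. Synteny anchors are extracted from genome-wide
    multiple alignments (MAF), elements sharing flanking anchors are grouped
    into candidate clusters, per-cluster similarity graphs are edited to
    cographs and refined with a duplication-aware order-preserving alignment,
    and the resulting ortholog groups are mapped onto a species tree to count
    insertions, deletions, tandem duplications, singletons, missing data,
    pseudogenes and remolding events. Includes a benchmark generator with
    known ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
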