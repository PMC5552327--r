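Package: qtlgosem
Title: Semantic Similarity of Heterogeneous Traits from QTL Regions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links quantitative trait loci (QTL) for macroscopic, metabolite
    and expression traits to overrepresented Gene Ontology terms via Fisher
    exact tests with multi-region occurrence and generality filters, computes
    trait-trait semantic similarity from those term sets (Lin term similarity
    aggregated by best-match average), assesses significance with two
    permutation schemes (randomized genomic regions and shuffled trait-term
    links), and exports similarity networks and complete-linkage dendrograms.
    Includes a synthetic-data generator with planted functional signals so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
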