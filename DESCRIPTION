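Package: NLRIDscan
Title: Discovery of Plant NLR Immune Receptors with Integrated Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of plant nucleotide-binding leucine-rich-repeat
    (NLR) immune receptors and their integrated domains (NLR-IDs) from
    standard domain-scan tables, partitioning of NB-ARC phylogenies into
    clades by bootstrap support and branch-length depth, detection of
    head-to-head tandem NLR gene pairs with Fisher exact enrichment tests,
    and profiling of protein domain architectures around the integration
    site. Includes a synthetic-data generator that plants NLRs, tandem
    pairs, clade-structured trees and integrated domains with known ground
    truth so every stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    phangorn,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
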