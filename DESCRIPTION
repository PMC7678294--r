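Package: ltrcensus
Title: Census of LTR Retrotransposons with Read-Based and
    Hybridization-Based Copy-Number Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural detection of full-length LTR retrotransposons in
    assembled contigs by near-identical terminal-repeat pairing, grouping
    of detected elements into families by shared-word (dot-plot style)
    similarity with majority-vote consensus building, estimation of a
    family's genome proportion and copy number from unassembled shotgun
    reads, the slot-blot dilution-standard copy-number calculus (plasmid
    insert mass, dilution matching, ng target per microgram genomic DNA,
    copies per genome, solo-LTR ratio interpretation), and classification
    of insertion sites against gene models as exonic, intronic or
    intergenic. Includes a synthetic-genome module that plants element
    families with known ground truth, simulates shotgun reads and
    slot-blot intensity ladders, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
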