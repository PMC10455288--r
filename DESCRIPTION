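Package: pdelim
Title: Distance-Based Species and Genus Delimitation from Ribosomal DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for DNA-barcode-gap taxonomic delimitation of fungi from
    ribosomal DNA (ITS, 28S, 18S) multiple sequence alignments. Implements
    MEGA-compatible pairwise-deletion p-distances with column-bootstrap
    standard errors, gap-rich column filtering, single-linkage threshold
    clustering into species- and genus-level groups, representative sequence
    selection, a multi-locus rank-assignment rule engine with
    established/putative/inconclusive statuses, neighbor-joining scaffold
    trees with bootstrap support, multi-locus supermatrix concatenation, and
    a truth-labelled Jukes-Cantor simulator of hierarchical multi-locus
    divergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
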