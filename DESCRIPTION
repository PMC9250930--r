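Package: triadkit
Title: Cataloguing Homoeologous Gene Families in Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide cataloguing of a gene family in an
    allopolyploid such as hexaploid wheat: merging and curating candidate-gene
    evidence, inferring homoeolog groups (triads, diads, tetrads, singletons)
    from per-subfamily gene trees and physical positions, assigning systematic
    subgenome-aware gene names, classifying homoeolog expression bias on the
    ternary simplex into seven categories, calling tissue-specific expression,
    and annotating marker-trait-association SNPs with nearby family members.
    Includes a synthetic-data generator with planted ground truth so every
    stage is testable without external downloads, and packaged reference
    tables for the wheat nitrate-transporter families (NPF, NRT2, CLC,
    SLAC1/SLAH).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    methods,
    stats,
    tools,
    utils,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
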