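Package: barcodegap
Title: Barcode Gap Discovery and Alignment-Sensitivity Analysis for DNA
    Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting operational taxonomic units (OTUs) from
    DNA barcode alignments by automatic barcode-gap discovery, and for
    quantifying how sensitive the resulting OTU counts are to the upstream
    multiple-sequence-alignment algorithm and to the evolutionary distance
    correction. Implements pairwise p, Kimura 2-parameter, Tamura-Nei (TN93)
    and General Time Reversible (GTR) distances under pairwise deletion with
    optional gamma-rate and invariant-site adjustments, ranked-distance gap
    detection with initial and recursive partitioning over a sweep of prior
    intraspecific divergences, neighbor-joining trees with Fitch parsimony
    diagnostics (tree length, consistency and retention indices, minimum
    evolution score, g1 signal statistic), alignment site statistics, and a
    seeded simulator of ITS-like barcode datasets with known species
    partitions and an explicit indel process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
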