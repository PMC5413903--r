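Package: clonetrace
Title: Clonal Lineage Tracing of Cell Reprogramming with Lentiviral DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for split-dish cellular-barcoding experiments that ask
    whether sister cells share reprogramming fate. Provides a synthetic-data
    generator for barcoded lineage experiments (random barcode libraries,
    clonal division, four-dish splitting, loss of material, quota-driven
    reprogramming with heritable sister fate, PCR/sequencing noise, FASTQ
    output with spike-in controls), a barcode-recovery pipeline
    (demultiplexing by dish signature, flank trimming, quality and length
    filters, greedy edit-distance clustering, cross-dish filters, overlap
    tables), closed-form estimators (Poisson MOI, mark-recapture library
    diversity, expected shared barcodes), a stochastic agent-based simulator
    of the experiment, and a grid-fitting procedure that estimates the
    probability that sister cells reprogramme synchronously (the
    heritability level) by Kruskal-Wallis compatibility between simulated
    and observed overlap counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
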