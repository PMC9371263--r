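Package: barcodelib
Title: Construction and Audit of Multi-Marker DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Library", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to build, curate and audit DNA barcode reference libraries
    for mitochondrial markers (COI, 16S, ND2): tabular and GenBank-flatfile
    ingestion, duplicate/fragment/geography curation with a NUMT screen,
    uncorrected p-distances with pairwise deletion over affine-gap pairwise
    alignments, taxonomy-partitioned distance summaries and barcode-gap
    statistics, deep-lineage and shared-haplotype anomaly flags,
    threshold-based species assignment against reference panels with
    cross-marker label transfer and syntopy reports, neighbor-joining tree
    construction with reciprocal-monophyly screening, and a seeded synthetic
    library generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
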