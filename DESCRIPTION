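Package: AbLineage
Title: Unseeded Clonal Lineage Assignment for Antibody Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for unseeded clonal lineage assignment in antibody
    (BCR heavy chain) repertoire sequencing data. Implements an
    antibody-specific pairwise distance combining length-normalized
    weighted CDR3 edit distance, variable/joining gene-use penalties and
    a shared somatic-mutation bonus; hierarchical clustering of the
    resulting distance matrix into clonal lineages; data-driven
    calibration of the clustering threshold from the trough of the
    pairwise-score histogram; UAID (UMI) consensus error correction of
    barcoded reads; a ground-truth repertoire simulator with somatic
    hypermutation, amplification bias and sequencing error; and
    evaluation utilities (clonality, cross-donor contamination,
    pairwise precision/recall, germline usage, lineage network graphs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    igraph,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
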