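Package: contrastPeaks
Title: Replicate-Contrastive Peak Calling for ATAC-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An unsupervised peak caller for replicated ATAC-seq experiments.
    Candidate enriched regions are selected from multi-replicate fragment
    coverage by per-chromosome thresholding, merging and length filtering;
    fixed-length coverage segments extracted from the candidates are embedded
    by a one-dimensional convolutional residual autoencoder trained jointly
    under a replicate contrastive loss, a class-similarity loss and a
    reconstruction loss; per-segment peak probabilities are averaged into
    region scores and emitted as scored peak calls. Includes a fragment-level
    coverage simulator with planted peaks, and label-transfer evaluation
    utilities (weighted score transfer, precision/recall/F1, precision-recall
    curves and their area).
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: ATACSeq, PeakDetection, Epigenetics, Sequencing
RoxygenNote: 7.3.3
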