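Package: mapdmr
Title: Differential Methylation Region Calling for MBD Affinity
    Purification Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies differentially methylated regions (DMRs) from
    MBD-affinity-purification sequencing (MAP-seq/MBD-seq) coverage.
    Implements the full calling strategy: per-sample peak finding, cross-sample
    merging and repeat exclusion into MAP-regions, abutting 50-bp window depth
    matrices, ratio-to-reference quantile normalization, empirical-Bayes
    moderated window statistics with Benjamini-Hochberg correction, and
    knitting of significant windows into DMRs. Also provides DMR
    characterization (sequence composition, genomic annotation hierarchy,
    CpG-island co-localization, chromosome-arm distribution), an
    inter-individual methylation-variance metric, sample clustering and PCA
    sanity checks, and a synthetic methylome generator with ground-truth
    spike-ins for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    Biostrings,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
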