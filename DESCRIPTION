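Package: piatac
Title: Protein-Indexed Single-Cell ATAC-seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis for protein-indexed single-cell ATAC-seq
    (Pi-ATAC), where each sorted cell carries both a chromatin accessibility
    profile and index-FACS protein intensities. Implements peak-level region
    filtering and summit-centred peak selection, fragment-in-peak counting,
    barnyard species classification and per-cell quality filters; motif and
    k-mer peak annotation; bias-corrected transcription-factor deviation
    z-scores against GC- and accessibility-matched background peak sets with
    per-motif variability tests; protein-stain grouping, protein-deviation
    correlation, group comparisons, Hartigans' dip test of bimodality and
    down-sampling controls; pseudo-bulk aggregation and information-content
    curves; and a synthetic-data generator with known ground truth so that
    every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
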