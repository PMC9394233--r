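Package: ctcnv
Title: Copy Number Profiling of Single Circulating Tumour Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline for copy-number-variation profiling of single
    circulating tumour cells (CTCs) from low-pass whole-genome sequencing.
    Reads are counted in fixed-width genomic bins, normalized and corrected
    for GC content and mappability, cleaned of shared "wave" bias by
    regression against a calibration panel of copy-number-neutral single
    cells, segmented by circular binary segmentation, and called into
    discrete loss/neutral/gain/amplification states with per-state
    posterior probabilities. Called profiles are condensed into
    constant-call regions and clustered hierarchically to expose
    intrapatient tumour heterogeneity. A quality-control layer provides
    multiplex-band QC scoring, a chromosome-arm read-distribution statistic
    for detecting failed whole-genome amplification, MAD noise metrics,
    empty-bin rejection, subsampling-based minimum-depth determination and
    paired Wilcoxon method comparisons. A synthetic-data module simulates
    single-cell bin counts with clone structure, wave and GC bias,
    overdispersion, bin dropout and failed-WGA read collapse so that every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
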