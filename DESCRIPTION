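Package: chipscan
Title: Sliding-Window ChIP-Seq Peak Calling on Binned Coverage Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts mapped ChIP-seq reads (SAM, Bowtie or BED format) into
    normalized, smoothed, per-chromosome binned coverage tracks with
    PCR-duplicate filtering and fractional weighting of multi-mapped reads;
    calls protein-binding peaks against an input control with a five-threshold
    sliding-window test built around a one-sided Wilcoxon rank-sum statistic;
    estimates an empirical false discovery rate by ChIP/control sample swap;
    writes wiggle-family track files and BED-compatible peak lists; and renders
    read-distribution bar-graph figures with gene annotation and peak
    highlighting. A seeded read simulator with planted peaks, PCR duplicates
    and multi-mapping repeat loci provides ground-truth data for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
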