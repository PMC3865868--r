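Package: knowyourdata
Title: Quality Assessment Toolkit for High-Throughput Sequencing Runs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cross-platform quality assessment for high-throughput sequencing
    runs. Provides canonical k-mer counting and k-mer spectrum analysis
    (error-peak detection, heterozygosity flagging and genome-size
    estimation), k-mer based contamination screening and filtering against
    reference k-mer tables, Nextera long-mate-pair junction-adaptor detection
    and clipping with duplicate-rate and orientation profiling, demultiplexing
    of offset inline-barcoded (RAD-style) libraries, per-base and Q30 read
    metrics, and a per-run/per-base/per-range QC metric store with parsers for
    FastQC-format reports. A built-in seeded simulator generates genomes,
    error-bearing reads, contaminant-spiked mixtures, long-mate-pair libraries
    and barcoded reads together with ground-truth tables, so every analysis is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
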