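Package: readqa
Title: Quality Assessment and Filtering of Short Sequencing Reads
Version: 1.0.0
Authors@R: person("QA", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Headless quality assessment for second-generation sequencing
    reads of uniform length. Parses multifasta-style phred quality files and
    matching sequence files (nucleotide FASTA or SOLiD color-space csfasta),
    validates records against an expected read length while logging every
    eliminated record, accumulates per-base quality frequency tables and
    read-level mean/median distributions in a single pass, filters read pairs
    by mean or median phred quality at a chosen cutoff, estimates fold
    genome coverage before and after filtering, and emits synchronized
    ".new" filtered files, chart-ready series, static plots and
    machine-readable summaries. Includes a deterministic synthetic read
    generator for testing the whole pipeline without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
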