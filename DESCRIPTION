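Package: splitpool
Title: Demultiplexing of Split-and-Pool Combinatorially Barcoded Reads
Version: 0.1.0
Authors@R:
    person("splitpool", "developers", email = "splitpool@example.org",
           role = c("aut", "cre"))
Description: Detects sequentially ligated barcode strings in sequencing
    reads by exact, positionally constrained matching, tolerating linker
    length drift, skipped ligation rounds, untrimmed adapter residues and
    reverse-complement orientation. Routes every read of a FASTQ file to
    exactly one per-cell output file named by its barcode combination,
    and reports per-read and aggregate ligation diagnostics (category
    fractions, linker-length histograms, per-well usage) for optimizing
    split-and-pool laboratory workflows. Includes a synthetic read
    generator with ground truth emulating the error structure of
    long-read split-and-pool libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
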