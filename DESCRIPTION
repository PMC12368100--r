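Package: trnacharge
Title: Simulation and Classification of tRNA Aminoacylation from Nanopore Signal
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying tRNA aminoacylation ("charging") with nanopore
    direct RNA sequencing of adapter-ligated tRNAs. Provides construction of
    extended tRNA references (5' adapter + tRNA body + CCA + 3' adapter) with
    anchored charge-site coordinates; an event-level squiggle simulator with
    amino-acid-specific current depression at the charge site, dwell-time
    inflation nine positions downstream, aberrant read truncation
    ("unblocking"), elevated basecall error around the embedded amino acid,
    and translocation-time sampling bias; reference-anchored per-position
    signal metrics (dwell, trimmed-mean normalized current); a per-read
    charging classifier emitting 0-255 modification-likelihood scores and
    pairwise amino-acid classifiers; and per-isodecoder differential charging
    and abundance statistics (two-proportion Z-tests with Benjamini-Hochberg
    correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
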