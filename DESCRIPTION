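Package: consensr
Title: Consensus Read Generation and UMI-Aware Deduplication for
    Paired-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Streams coordinate-sorted paired-end alignments, clusters read
    pairs by mapping position and (optionally) unique molecular identifier
    (UMI), and merges each cluster into a single error-suppressed consensus
    read pair using a quality-aware base-scoring scheme with reference-genome
    fallback. Dual (duplex) UMIs in reciprocal orientation are recognised as
    the two strands of one original DNA fragment. Reports duplication,
    coverage and mismatch statistics as machine-readable JSON and as a
    standalone interactive HTML page, and ships a ground-truthed synthetic
    fixture generator (cfDNA-like fragment lengths, PCR duplicates, Phred
    quality model) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
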