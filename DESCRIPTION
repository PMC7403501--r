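Package: koverlap
Title: Long-Read Overlap Detection from the k-mer Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("koverlap", "developers", email = "koverlap@example.org",
           role = c("aut", "cre"))
Description: All-vs-all overlap detection for noisy long reads (PacBio SMRT,
    Oxford Nanopore). Solid k-mers are selected from the dataset-wide k-mer
    frequency spectrum to discard both error-induced and repeat-derived seeds,
    shared solid k-mers between read pairs are chained under collinearity
    constraints with a two-stage consistency test (short seeds rescue large
    anchor gaps), and candidate overlaps are boundary-revised and accepted by
    length and balance conditions. Reads FASTA/FASTQ, writes PAF. Includes a
    long-read simulator with ground-truth overlaps and a precision/recall/F1
    scorer for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
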