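Package: condmer
Title: Conditional (m,n)-mer Frequency Features for Nucleotide Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free feature extraction for nucleotide sequences based
    on conditional oligonucleotide frequencies. An (m,n)-mer feature is the
    conditional probability of an n-mer suffix given its immediately
    preceding m-mer context; after normalization it has the same length and
    range as the plain (m+n)-mer frequency vector and can replace it in any
    downstream tool. The package provides base-4 mer encoding, windowed
    counting with ambiguity handling, sequence filtering and fragmentation,
    FASTA input and feature-matrix CSV output, a stationary Markov-chain
    sequence simulator for benchmarking, and a resampled
    classification/clustering evaluation harness (AUC, adjusted Rand index,
    win/tie/loss tests between feature families).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    glmnet,
    kernlab,
    ranger,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
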