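Package: atachmm
Title: Hidden Markov Model Peak Calling for Paired-End ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes a paired-end ATAC-seq dataset into nucleosome-free
    and nucleosomal signal layers using an EM-fitted fragment-length mixture
    (one exponential plus three Gaussian components), learns a three-state
    hidden Markov model of accessible-chromatin structure with multivariate
    Gaussian emissions over the four signal tracks, and decodes the genome
    with the Viterbi algorithm to call accessible regions in gappedPeak
    format with coverage-based scores and smoothed summits. Includes
    base-pair-level precision/recall/FPR evaluation with extreme-point AUC,
    and a synthetic paired-end fragment simulator with known truth labels
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
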