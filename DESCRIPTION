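Package: cpgoe
Title: CpG Observed/Expected Signatures of Historical DNA Methylation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the sequence signature that historical germ-line DNA
    methylation leaves in a genome. Computes the normalised CpG content
    (CpG[o/e] = N*CpG/(C*G)) of gene bodies and of 1-kb genome fragments,
    fits univariate Gaussian mixtures to the resulting distributions by
    expectation-maximisation, selects the number of components by the
    Bayesian information criterion, and calls the presence (bimodal) or
    absence (unimodal) of a historical methylation signature. Includes a
    first-order Markov sequence simulator with controlled CpG depletion
    that generates transcript sets and annotated toy genomes, so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
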