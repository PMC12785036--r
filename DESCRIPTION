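Package: wickerformer
Title: Sparse-Attention Transformer Classification of Transposable Element Consensus Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies transposable-element (TE) consensus DNA sequences into
    the sixteen Wicker superfamilies with an encoder-only transformer that uses
    sliding-window local attention plus designated global-attention positions.
    Sequences are tokenized into overlapping k-mers with a dynamically dilated
    sliding window, over-long inputs are processed in chunks whose class
    probabilities are median-aggregated, and training uses on-the-fly
    biologically motivated augmentation with weighted cross-entropy to counter
    class imbalance. Includes labeled-FASTA handling with stratified
    train/validation/test splits, a full evaluation suite (per-class
    precision/recall/F1, macro and support-weighted averages), threshold-filtered
    TSV-producing inference, and a synthetic TE-family generator so the whole
    pipeline is exercisable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
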