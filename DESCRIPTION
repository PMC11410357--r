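Package: morphodecode
Title: Decoding Evoked Brain Responses to Multimorphemic Words with
    Compositional Subword Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for testing whether evoked magnetoencephalography (MEG)
    responses to morphologically complex written words can be decoded from
    word vectors composed as sums of subword-segment embeddings. Provides
    word segmentation schemes (whole-word, character n-grams, random splits,
    external morphological lexicons), a minimal skip-gram trainer for
    segment vectors, ridge-regression decoding with per-dimension
    regularization over sliding time windows, the leave-two-out 2-vs-2
    classification test, and the word-label and segment-label permutation
    nulls that separate morphologically informative segmentations from
    decoding driven by shared-segment structure. A synthetic-data module
    simulates multimorphemic lexicons, structured segment vectors, toy
    corpora, and evoked responses as noisy linear projections of composed
    word vectors, so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
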