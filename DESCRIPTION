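Package: chemner
Title: Chemical Named Entity Recognition and Resolution to a ChEBI-Style Lexicon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition of chemical entity mentions in text and their
    resolution to identifiers of a ChEBI-style chemical lexicon. Provides a
    chemistry-aware tokenizer, a five-tag sequence encoding with
    stem/prefix/suffix/number features, a linear-chain conditional random
    field tagger with a leave-one-document-out protocol, a dictionary
    (exact-match) baseline recognizer, a two-stage lexical resolver combining
    exact descriptor matching with an evidence-content-weighted Jaccard
    partial match, a five-mode boundary-matching evaluator, and a synthetic
    corpus and lexicon generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
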