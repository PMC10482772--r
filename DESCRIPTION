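Package: contextsim
Title: Dynamic Contextual Semantic Similarity from Word Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-token contextual semantic similarity scores for
    reading-time research. Implements a dynamic measure that sums the
    lower-triangle Pearson correlations among the embedding vectors of a
    target word and its preceding context words, together with five
    comparison measures based on cosine similarity to summed context
    vectors and inverse Euclidean distance to averaged context vectors.
    Includes a reader for word2vec/fastText plain-text embedding tables,
    deterministic tokenization and context-window extraction with
    content/function word classification, synthetic generators for
    embeddings, passages and fixation durations, and a lightweight
    participant-centered regression for recovering similarity effects on
    simulated eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
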