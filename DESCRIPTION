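Package: embedalign
Title: Structure-Aware Protein Search and Differentiable Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Embedding-based remote-homology tools for protein sequences: a
    differentiable Needleman-Wunsch alignment layer with exact custom
    derivatives (smoothed max/argmax forward pass, expected-alignment
    backward pass, directional derivatives and training adjoints),
    convolutional match/gap scoring heads over per-residue embeddings, a
    twin transformer encoder trained so the cosine similarity of two
    protein vectors approximates their structural similarity (TM-score),
    an indexed vector database for structure-aware k-nearest-neighbour
    search, alignment and retrieval evaluation metrics, and a seeded
    synthetic-homolog generator so the whole stack is testable offline
    with a deterministic toy embedder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
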