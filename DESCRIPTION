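Package: munk
Title: Cross-Species Protein Network Embeddings from Landmark Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Embeds proteins from two or more species' protein-protein
    interaction networks into a single shared vector space. A regularized
    Laplacian diffusion kernel is computed per network, the source kernel is
    factorized into reproducing-kernel Hilbert space coordinates, and target
    proteins are placed in the same space by a minimum-norm landmark solve
    anchored at homologous protein pairs. Cross-species inner products serve
    as functional similarity scores. Includes downstream machinery for
    cross-species functional-similarity evaluation (Resnik semantic
    similarity, Hungarian matching with Gene Ontology consistency,
    k-functional similarity with AUPR, degree-preserving permutation nulls,
    multi-species function prediction), multi-species synthetic-lethality
    classification on summed pair representations, generalized phenolog
    scanning, and seed-deterministic synthetic-data generators for all
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    e1071,
    graphics,
    grDevices,
    igraph,
    pROC,
    randomForest,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
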