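Package: phenorag
Title: Knowledge-Graph Retrieval-Augmented Generation for Phenotype-Driven
    Rare-Disease Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a typed facial phenotype-gene-disease property
    graph and evaluates retrieval-augmented language-model diagnosis against
    it.  Provides seven graph-embedding algorithms (spectral Laplacian,
    modularity, NetMF, random projection, and three random-walk skip-gram
    variants) behind one interface, a node-classification harness for
    embedding selection, two graph retrievers (a Cypher-subset pattern
    matcher and an embedding-based retriever that inserts the query as a
    transient node), a seeded mock language model, builders for selective and
    non-selective diagnostic benchmarks, and an evaluation suite computing
    accuracy over repeats, answer consistency, keypoint coverage, and
    temperature-induced variability with its reduction under retrieval
    augmentation.  A synthetic-data generator produces schema-valid graphs
    and case records with controllable phenotype overlap so the whole
    pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    yaml
Config/testthat/edition: 3
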