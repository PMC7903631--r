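Package: ontorec
Title: Hybrid Semantic Recommender for Ontology-Annotated Items
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid recommender framework for items annotated in an
    ontology, such as chemical compounds in a ChEBI-like is_a hierarchy.
    Parses OBO ontologies into a directed acyclic graph, computes
    information content and the Resnik, Lin and Jiang-Conrath semantic
    similarity measures, and precomputes all pairwise similarities into a
    persistent cache. Provides implicit-feedback collaborative filtering
    (alternating least squares with confidence weighting, and Bayesian
    personalized ranking), a content-based scorer that rates a candidate
    item by its mean semantic similarity to the n most similar of a
    user's known items, and two weighted hybrid fusion rules (product and
    mean). Includes a five-fold user-by-item cross-validated top-k
    evaluation protocol (precision, recall, F-measure, mean reciprocal
    rank, normalized discounted cumulative gain) and a seeded synthetic
    generator of DAG ontologies and ontology-correlated implicit ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
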