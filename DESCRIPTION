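Package: hvsm
Title: Hierarchical Vector Space Model for Gene Ontology Functional Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes functional similarity between genes or gene products
    from their Gene Ontology (GO) annotations using a hierarchical vector
    space model: binary annotation vectors are expanded over is_a/part_of
    parents, grandparents and common descendants with relation-specific
    contribution factors, and the cosine similarity is calibrated by a
    certainty factor depending on annotation counts. Includes parsers for
    OBO ontologies and GAF annotation files, classic comparison measures
    (basic VSM, IntelliGO, Resnik, Lin, Jiang, Schlicker, SimGIC, Jaccard,
    Dice with MAX/AVG/BMA combination), ROC/AUC evaluation of similarity
    scores as protein-protein interaction classifiers, and a seeded
    generator of synthetic ontologies, annotation sets and labelled
    gene-pair benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
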