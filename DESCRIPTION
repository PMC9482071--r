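Package: pathcoke
Title: Contextual Knowledge Graph Embeddings with Causal Multihop Path Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representation learning on clinical knowledge graphs of
    diseases, symptoms, drugs and mechanisms. Mines multihop relation paths
    under causal-constraint composition rules, trains a contextual transformer
    embedding model by masked entity prediction over edge and path sequences,
    compresses it to a compact student model with three-level knowledge
    distillation (embedding, attention/hidden-state, temperature-softened
    prediction), evaluates by filtered link prediction and path-query
    answering (MRR, Hits@N), and feeds the learned embeddings to a multilabel
    syndrome-diagnosis classifier. Includes a seeded synthetic graph generator
    with planted compositional structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
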