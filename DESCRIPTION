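Package: ppisent
Title: Protein-Protein Interaction Prediction from GO-Term Protein Sentences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions by representing each
    protein as a "sentence" of Gene Ontology (GO) term embedding vectors and
    classifying protein pairs with a convolutional sentence-encoder pair
    model. Annotations are read from GAF files, filtered by evidence-code
    reliability, and optionally weighted by annotation duplication counts;
    GO-term vectors are learned with skip-gram negative sampling over
    ontology axiom sentences. Also provides the classic GO-structure
    semantic-similarity baselines (Resnik, Lin, Pekar, Wang with AVG, Max
    and best-match-average aggregation), ROC/PR evaluation utilities, and a
    deterministic synthetic benchmark generator (ontology, annotations and
    labelled pair sets with planted co-annotation signal) so the whole
    pipeline runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
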