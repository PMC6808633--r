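Package: ontonorm
Title: Ontology Concept Normalization by Projecting Word Embeddings into Concept Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes textual entity mentions to ontology concepts by learning a
    linear projection from a distributional word-embedding space (the semantic space
    of the corpus) into a concept vector space derived from the ontology's is-a
    hierarchy (the semantic space of the ontology). Provides decay-weighted ancestor
    concept representations, graph-walk concept embeddings, PCA/MDS/SVD reduced
    variants, skip-gram/CBOW word embeddings with a character n-gram subword mode for
    out-of-vocabulary terms, cosine nearest-neighbour concept prediction, evaluation
    with Wang-style semantic similarity and a strict exact-match measure, decay and
    reduction sweep experiments, synthetic data generators, and readers/writers for
    OBO 1.2 ontologies, word2vec text vectors, and BioNLP-ST standoff annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
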