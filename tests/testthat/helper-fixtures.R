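# three-concept is-a chain: 0003 -> 0002 -> 0001 (root)
ch3_ontology <- function() {
  ontology(
    labels = c("OBT:0001" = "habitat", "OBT:0002" = "soil",
               "OBT:0003" = "forest soil"),
    parents = list("OBT:0001" = character(), "OBT:0002" = "OBT:0001",
                   "OBT:0003" = "OBT:0002")
  )
}

# diamond: C is_a A, C is_a B, A is_a R, B is_a R
diamond_ontology <- function(extra_c_to_r = FALSE) {
  pc <- c("A", "B")
  if (extra_c_to_r) pc <- c(pc, "R")
  ontology(
    labels = c(R = "root", A = "left", B = "right", C = "leaf"),
    parents = list(R = character(), A = "R", B = "R", C = pc)
  )
}

# memoization-free brute-force Wang S-values: enumerate every upward path
# from `a` and keep, per ancestor, the maximum of factor^path_length
oracle_s_values <- function(onto, a, factor) {
  best <- new.env(parent = emptyenv())
  walk <- function(node, len) {
    val <- factor^len
    cur <- get0(node, envir = best, ifnotfound = -Inf)
    if (val > cur) assign(node, val, envir = best)
    for (p in onto$parents[[node]]) walk(p, len + 1L)
  }
  walk(a, 0L)
  unlist(as.list(best))
}

oracle_wang <- function(onto, a, b, factor) {
  sa <- oracle_s_values(onto, a, factor)
  sb <- oracle_s_values(onto, b, factor)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# small deterministic training corpus about habitats
tiny_corpus <- function() {
  sentences <- c(
    "soil samples from forest soil", "bacteria grow in soil",
    "forest soil hosts fungi", "samples of gut flora",
    "human gut flora bacteria", "bacteria isolated from soil samples",
    "fungi live in forest soil", "gut bacteria in human samples"
  )
  lapply(rep(sentences, 15L), tokenize)
}

# shared 50-concept synthetic study fixture (built once per test run)
synth_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- synth_config(n_concepts = 50L, seed = 42L)
    onto <- generate_ontology(sc)
    gen <- generate_lexicon_corpus(onto, sc)
    emb <- train_word_embeddings(gen$corpus, dimension = 20L,
                                 mode = "skipgram", seed = 42L)
    ann <- gen$annotations
    train <- ann[ann$split == "train", ]
    held <- ann[ann$split == "heldout", ]
    train_pairs <- build_training_pairs(
      onto,
      tibble::tibble(surface = train$surface,
                     concept_ids = as.list(train$concept_id)),
      mode = "both"
    )
    eval_pairs <- tibble::tibble(
      mention_id = held$mention_id, tokens = held$tokens,
      concept_id = held$concept_id
    )
    cache <<- list(cfg = sc, onto = onto, gen = gen, emb = emb,
                   train_pairs = train_pairs, eval_pairs = eval_pairs)
    cache
  }
})
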