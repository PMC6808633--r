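#' Configuration for the synthetic benchmark generators
#'
#' Desk-scale stand-in for a habitat-normalization setup: a random is-a DAG
#' ontology of `n_concepts` concepts, a pseudo-word lexicon and corpus whose
#' sentences mix a concept's vocabulary with its parents' (so distributional
#' similarity mirrors ontological proximity by construction — the premise the
#' projection method relies on), annotated mentions with a held-out split,
#' and planted linear instances for projection-recovery checks.
#'
#' @param n_concepts Number of concepts (single root, topological DAG).
#' @param max_parents Maximum direct parents per concept (1 = tree).
#' @param words_per_concept Lexicon size per concept.
#' @param n_mentions Number of annotated mentions.
#' @param embed_dim Term-space dimension of planted instances.
#' @param noise_sigma Per-coordinate Gaussian noise of planted instances.
#' @param seed Integer seed; all generators are deterministic in (config, seed).
#' @param sentences_per_concept Corpus sentences generated per concept.
#' @param sentence_length Tokens per corpus sentence.
#' @param mixing Probability that a sentence token is drawn from a parent's
#'   lexicon instead of the concept's own.
#' @param heldout_fraction Fraction of mentions marked held-out.
#' @param oov_fraction Fraction of held-out mentions given a surface token
#'   absent from the training corpus (exercises the out-of-vocabulary path).
#' @param synonym_fraction Fraction of concepts given one synonym.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_concepts = 50L, max_parents = 2L,
                         words_per_concept = 3L, n_mentions = 200L,
                         embed_dim = 20L, noise_sigma = 0,
                         seed = 1L, sentences_per_concept = 20L,
                         sentence_length = 8L, mixing = 0.3,
                         heldout_fraction = 0.3, oov_fraction = 0.1,
                         synonym_fraction = 0.2) {
  stopifnot(n_concepts >= 1L, max_parents >= 1L, words_per_concept >= 1L,
            n_mentions >= 1L, embed_dim >= 1L, noise_sigma >= 0,
            mixing >= 0, mixing <= 1, heldout_fraction >= 0,
            heldout_fraction < 1, oov_fraction >= 0, oov_fraction <= 1)
  structure(
    list(
      n_concepts = as.integer(n_concepts), max_parents = as.integer(max_parents),
      words_per_concept = as.integer(words_per_concept),
      n_mentions = as.integer(n_mentions), embed_dim = as.integer(embed_dim),
      noise_sigma = noise_sigma, seed = as.integer(seed),
      sentences_per_concept = as.integer(sentences_per_concept),
      sentence_length = as.integer(sentence_length), mixing = mixing,
      heldout_fraction = heldout_fraction, oov_fraction = oov_fraction,
      synonym_fraction = synonym_fraction
    ),
    class = "synth_config"
  )
}

# seeded pseudo-word generator; the `used` environment rules out collisions
.pseudo_words <- function(n, used, min_len = 5L, max_len = 8L) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(min_len:max_len, 1L)
      w <- paste(sample(letters, len, replace = TRUE), collapse = "")
      if (is.null(get0(w, envir = used, inherits = FALSE))) {
        assign(w, TRUE, envir = used)
        out[[i]] <- w
        break
      }
    }
  }
  out
}

#' Generate a random is-a DAG ontology
#'
#' Concepts `SYN:000001 ... SYN:n` with the first concept as the sole root;
#' every later concept draws 1 to `max_parents` parents uniformly from the
#' concepts before it, so acyclicity holds by construction. Labels (and a
#' fraction of synonyms) are seeded pseudo-words.
#'
#' @param cfg A [synth_config()].
#' @return An [ontology()] object.
#' @export
generate_ontology <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_concepts
  ids <- sprintf("SYN:%06d", seq_len(n))
  used <- new.env(parent = emptyenv())
  labels <- stats::setNames(.pseudo_words(n, used), ids)
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[[1L]]]] <- character()
  if (n > 1L) {
    for (i in 2:n) {
      np <- sample.int(min(cfg$max_parents, i - 1L), 1L)
      parents[[ids[[i]]]] <- ids[sample.int(i - 1L, np)]
    }
  }
  synonyms <- list()
  n_syn <- round(cfg$synonym_fraction * n)
  if (n_syn > 0L) {
    with_syn <- ids[sample.int(n, n_syn)]
    for (c_id in with_syn) synonyms[[c_id]] <- .pseudo_words(1L, used)
  }
  ontology(labels = labels, parents = parents, synonyms = synonyms)
}

#' Generate a planted lexicon, corpus and annotations for an ontology
#'
#' Each concept receives `words_per_concept` pseudo-words. Corpus sentences
#' for a concept draw each token from the concept's own lexicon with
#' probability `1 - mixing` and from a random direct parent's lexicon
#' otherwise, so co-occurrence statistics reflect the hierarchy. Annotations
#' sample a concept and use 1--2 of its lexicon words as the mention surface;
#' a `heldout_fraction` of them is marked `split = "heldout"`, and an
#' `oov_fraction` of those held-out mentions gets one surface token replaced
#' by a derived word (a corpus word plus a suffix) that never occurs in the
#' corpus, exercising the out-of-vocabulary path with subword overlap.
#'
#' @param onto An [ontology()] (typically from [generate_ontology()]).
#' @param cfg A [synth_config()].
#' @return List with `corpus` (list of token vectors), `annotations` (tibble
#'   `mention_id`, `surface`, `tokens`, `concept_id`, `split`) and `lexicon`
#'   (named list concept -> words).
#' @export
generate_lexicon_corpus <- function(onto, cfg = synth_config()) {
  stopifnot(inherits(onto, "ontology"), inherits(cfg, "synth_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  concepts <- onto$concepts
  used <- new.env(parent = emptyenv())
  for (w in c(unname(onto$labels), unlist(onto$synonyms, use.names = FALSE))) {
    assign(w, TRUE, envir = used)
  }
  # the concept's label heads its lexicon, so labels are distributionally
  # grounded in the corpus (the premise behind label-based training pairs)
  lexicon <- stats::setNames(
    lapply(concepts, function(c_id) {
      c(unname(onto$labels[[c_id]]),
        if (cfg$words_per_concept > 1L) {
          .pseudo_words(cfg$words_per_concept - 1L, used)
        })
    }),
    concepts
  )

  corpus <- list()
  for (c_id in concepts) {
    pars <- onto$parents[[c_id]]
    for (s in seq_len(cfg$sentences_per_concept)) {
      sent <- character(cfg$sentence_length)
      for (t in seq_len(cfg$sentence_length)) {
        pool <- if (length(pars) > 0L && stats::runif(1L) < cfg$mixing) {
          lexicon[[pars[[sample.int(length(pars), 1L)]]]]
        } else {
          lexicon[[c_id]]
        }
        sent[[t]] <- pool[[sample.int(length(pool), 1L)]]
      }
      corpus[[length(corpus) + 1L]] <- sent
    }
  }

  n_m <- cfg$n_mentions
  ann_concepts <- concepts[sample.int(length(concepts), n_m, replace = TRUE)]
  split <- rep("train", n_m)
  n_held <- round(cfg$heldout_fraction * n_m)
  if (n_held > 0L) split[sample.int(n_m, n_held)] <- "heldout"
  tokens <- vector("list", n_m)
  for (i in seq_len(n_m)) {
    lex <- lexicon[[ann_concepts[[i]]]]
    k <- sample.int(min(2L, length(lex)), 1L)
    tokens[[i]] <- lex[sample.int(length(lex), k)]
  }
  held_idx <- which(split == "heldout")
  n_oov <- round(cfg$oov_fraction * length(held_idx))
  if (n_oov > 0L) {
    for (i in held_idx[sample.int(length(held_idx), n_oov)]) {
      j <- sample.int(length(tokens[[i]]), 1L)
      tokens[[i]][[j]] <- paste0(tokens[[i]][[j]], "oid")  # absent from corpus
    }
  }
  annotations <- tibble::tibble(
    mention_id = sprintf("T%d", seq_len(n_m)),
    surface = vapply(tokens, paste, character(1L), collapse = " "),
    tokens = tokens,
    concept_id = ann_concepts,
    split = split
  )
  list(corpus = corpus, annotations = annotations, lexicon = lexicon)
}

#' Generate a planted linear instance for projection-recovery checks
#'
#' Draws a well-conditioned linear map `G` (orthonormal rows/columns from a
#' QR decomposition of a Gaussian matrix) from the concept space into an
#' `embed_dim`-dimensional term space and emits one noisy image per concept:
#' `x_c = G y_c + N(0, noise_sigma)`. A second, independently noised copy of
#' the images is returned as held-out queries, so recovery can be measured
#' off the training draw. Returning `G` allows recovery checks against the
#' fitted projection.
#'
#' @param onto An [ontology()] object (supplies the concept order).
#' @param sso A [concept_space()] over the same concepts.
#' @param cfg A [synth_config()] (`embed_dim`, `noise_sigma`, `seed`).
#' @return List with `x` (n_concepts x embed_dim matrix, rownames =
#'   concepts), `x_heldout` (same shape, independent noise), `concepts`,
#'   and `true_map` (`embed_dim` x sso dim).
#' @export
generate_planted_instance <- function(onto, sso, cfg = synth_config()) {
  stopifnot(inherits(onto, "ontology"), inherits(sso, "concept_space"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 2L)
  d_sso <- ncol(sso$matrix)
  d_emb <- cfg$embed_dim
  if (d_emb <= d_sso) {
    q <- qr.Q(qr(matrix(stats::rnorm(d_sso * d_emb), d_sso, d_emb)))
    g <- t(q)  # orthonormal rows
  } else {
    q <- qr.Q(qr(matrix(stats::rnorm(d_emb * d_sso), d_emb, d_sso)))
    g <- q     # orthonormal columns
  }
  signal <- sso$matrix %*% t(g)
  noised <- function() {
    if (cfg$noise_sigma > 0) {
      signal + matrix(stats::rnorm(length(signal), sd = cfg$noise_sigma),
                      nrow(signal), ncol(signal))
    } else {
      signal
    }
  }
  x <- noised()
  x_heldout <- noised()
  rownames(x) <- rownames(sso$matrix)
  rownames(x_heldout) <- rownames(sso$matrix)
  list(x = x, x_heldout = x_heldout, concepts = rownames(sso$matrix),
       true_map = g)
}

#' Write a synthetic corpus as plain text, one sentence per line
#'
#' @param corpus List of token vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, character(1L), collapse = " "), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a plain-text corpus, one sentence per line
#'
#' @param path Input path.
#' @return List of token vectors (each line tokenized).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, tokenize)
}
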