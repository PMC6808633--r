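#' Assemble (term, concept) training pairs
#'
#' Builds the association pairs the projection is trained on. In supervised
#' mode the given corpus annotations are used, with multi-concept annotations
#' expanded to one pair per concept. In unsupervised mode no annotations are
#' needed: each concept contributes its label (and, by default, each synonym)
#' paired with itself — the intrinsic associations that make training
#' possible with no annotated corpus at all. `mode = "both"` concatenates.
#'
#' @param onto An [ontology()] object.
#' @param annotations Tibble/data frame of corpus annotations with columns
#'   `surface` (character) and `concept_ids` (list of character vectors);
#'   required for modes `"supervised"` and `"both"`.
#' @param mode One of `"supervised"`, `"unsupervised"`, `"both"`.
#' @param include_synonyms Include concept synonyms in unsupervised pairs.
#' @return A tibble with columns `surface`, `tokens` (list), `concept_id`,
#'   `source` (`corpus_annotation`, `concept_label` or `concept_synonym`).
#' @export
build_training_pairs <- function(onto, annotations = NULL,
                                 mode = c("unsupervised", "supervised", "both"),
                                 include_synonyms = TRUE) {
  stopifnot(inherits(onto, "ontology"))
  mode <- match.arg(mode)
  out <- list()

  if (mode %in% c("supervised", "both")) {
    if (is.null(annotations) || nrow(annotations) == 0L) {
      stop("mode = \"", mode, "\" requires annotations")
    }
    ids <- annotations$concept_ids
    if (is.null(ids)) ids <- as.list(annotations$concept_id)
    bad <- setdiff(unlist(ids, use.names = FALSE), onto$concepts)
    if (length(bad) > 0L) {
      stop("annotation concept(s) absent from the ontology: ",
           paste(unique(bad), collapse = ", "))
    }
    n_per <- vapply(ids, length, 1L)
    out$sup <- tibble::tibble(
      surface = rep(annotations$surface, n_per),
      tokens = lapply(rep(annotations$surface, n_per), tokenize),
      concept_id = unlist(ids, use.names = FALSE),
      source = "corpus_annotation"
    )
  }

  if (mode %in% c("unsupervised", "both")) {
    lab <- tibble::tibble(
      surface = unname(onto$labels),
      tokens = lapply(unname(onto$labels), tokenize),
      concept_id = onto$concepts,
      source = "concept_label"
    )
    out$lab <- lab
    if (include_synonyms) {
      n_syn <- vapply(onto$synonyms, length, 1L)
      if (sum(n_syn) > 0L) {
        syn_surface <- unlist(onto$synonyms, use.names = FALSE)
        out$syn <- tibble::tibble(
          surface = syn_surface,
          tokens = lapply(syn_surface, tokenize),
          concept_id = rep(onto$concepts, n_syn),
          source = "concept_synonym"
        )
      }
    }
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[vapply(res$tokens, length, 1L) > 0L, ]
}

#' Turn annotation pairs into a term-vector training matrix
#'
#' Computes one composed term vector per pair and drops pairs whose every
#' token is out of vocabulary (coverage 0) — those carry no usable signal and
#' are reported, not silently trained on.
#'
#' @param pairs A tibble from [build_training_pairs()] (columns `tokens`,
#'   `concept_id`).
#' @param emb A [train_word_embeddings()] result.
#' @return List with `x` (n x dimension matrix), `concepts` (length-n
#'   character), `coverage` (length-n numeric) and `n_rejected` (pairs dropped
#'   for zero coverage).
#' @export
pairs_to_matrix <- function(pairs, emb) {
  tv <- lapply(pairs$tokens, function(tk) term_vector(emb, tk))
  cov <- vapply(tv, `[[`, numeric(1L), "coverage")
  keep <- cov > 0
  x <- do.call(rbind, lapply(tv[keep], `[[`, "vector"))
  if (is.null(x)) x <- matrix(0, 0L, emb$dimension)
  list(
    x = x,
    concepts = pairs$concept_id[keep],
    coverage = cov[keep],
    n_rejected = sum(!keep)
  )
}
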