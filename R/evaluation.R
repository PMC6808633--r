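#' Configuration for the Wang-style semantic similarity
#'
#' The per-edge semantic contribution factor weights how much of a concept's
#' "S-value" survives each is-a step toward an ancestor. The conventional
#' default is 0.65; it is recorded in every evaluation report so runs stay
#' comparable.
#'
#' @param contribution_factor Real in (0,1).
#' @return A list of class `similarity_config`.
#' @export
similarity_config <- function(contribution_factor = 0.65) {
  if (!is.numeric(contribution_factor) || contribution_factor <= 0 ||
      contribution_factor >= 1) {
    stop("contribution_factor must be in (0, 1)")
  }
  structure(list(contribution_factor = contribution_factor),
            class = "similarity_config")
}

# Recursive S-values of concept `a`: S(a) = 1 and, for an ancestor t,
# S(t) = factor * max over children of t inside a's ancestor DAG of S(child).
# Memoized recursion over the induced (acyclic) sub-DAG.
.s_values <- function(onto, a, factor) {
  closure <- ancestors(onto, a)
  memo <- new.env(parent = emptyenv())
  assign(a, 1, envir = memo)
  s_of <- function(t) {
    v <- get0(t, envir = memo, inherits = FALSE)
    if (!is.null(v)) return(v)
    kids <- intersect(onto$children[[t]], closure)
    v <- factor * max(vapply(kids, s_of, numeric(1L)))
    assign(t, v, envir = memo)
    v
  }
  stats::setNames(vapply(closure, s_of, numeric(1L)), closure)
}

#' Wang-style semantic similarity between two concepts
#'
#' Computes the DAG-based similarity of Wang et al.: each concept's ancestor
#' closure gets recursively decayed S-values (1 at the concept itself,
#' multiplied by the contribution factor along each is-a edge, maximum over
#' paths), and the similarity is the sum of both concepts' S-values over the
#' shared ancestors divided by the sum of their total semantic values. The
#' result lies in (0,1] (any two concepts of a rooted DAG share at least one
#' ancestor) and equals 1 exactly when `a == b`.
#'
#' @param onto An [ontology()] object.
#' @param a,b Concept identifiers.
#' @param cfg A [similarity_config()].
#' @return Similarity in (0, 1]; symmetric in `a`, `b`.
#' @export
wang_similarity <- function(onto, a, b, cfg = similarity_config()) {
  stopifnot(inherits(onto, "ontology"), inherits(cfg, "similarity_config"))
  sa <- .s_values(onto, a, cfg$contribution_factor)
  sb <- .s_values(onto, b, cfg$contribution_factor)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# All pairwise Wang similarities between two concept sets, computing each
# concept's S-values once. Used by scoring and the random baseline.
.wang_matrix <- function(onto, from, to, cfg) {
  s_from <- lapply(from, .s_values, onto = onto, factor = cfg$contribution_factor)
  s_to <- lapply(to, .s_values, onto = onto, factor = cfg$contribution_factor)
  sv_from <- vapply(s_from, sum, numeric(1L))
  sv_to <- vapply(s_to, sum, numeric(1L))
  m <- matrix(0, length(from), length(to), dimnames = list(from, to))
  for (i in seq_along(from)) {
    for (j in seq_along(to)) {
      shared <- intersect(names(s_from[[i]]), names(s_to[[j]]))
      if (length(shared) > 0L) {
        m[i, j] <- sum(s_from[[i]][shared] + s_to[[j]][shared]) /
          (sv_from[[i]] + sv_to[[j]])
      }
    }
  }
  m
}

#' Score predictions against reference normalizations
#'
#' Two metrics per mention, aggregated as means: the semantic score (Wang
#' similarity between the top-1 prediction and the reference; with several
#' reference concepts the maximum over them is taken) which rewards
#' near-misses, and the strict score which rewards only exact matches.
#' Mentions with `status = "no_vector"` count 0 under both metrics rather
#' than being dropped — dropping them would silently inflate the scores.
#'
#' @param preds List of [predict_concepts()] results, each carrying a
#'   `mention` identifier.
#' @param refs Named list: mention identifier -> non-empty character vector
#'   of reference concept identifiers.
#' @param onto An [ontology()] object.
#' @param cfg A [similarity_config()].
#' @return Object of class `evaluation_report`: `semantic_score`,
#'   `strict_score`, `n_mentions`, `n_no_vector`, `records` (one row per
#'   mention) and `cfg`.
#' @export
score_predictions <- function(preds, refs, onto, cfg = similarity_config()) {
  stopifnot(inherits(onto, "ontology"))
  mention_ids <- vapply(preds, `[[`, character(1L), "mention")
  missing_ref <- setdiff(mention_ids, names(refs))
  if (length(missing_ref) > 0L) {
    stop("mention(s) without a reference entry: ",
         paste(missing_ref, collapse = ", "))
  }
  top1 <- vapply(preds, function(p) {
    if (p$status == "no_vector") NA_character_ else p$ranking$concept[[1L]]
  }, character(1L))
  ref_concepts <- unique(unlist(refs[mention_ids], use.names = FALSE))
  pred_concepts <- unique(top1[!is.na(top1)])
  wm <- if (length(pred_concepts) > 0L) {
    .wang_matrix(onto, pred_concepts, ref_concepts, cfg)
  } else NULL

  sim <- numeric(length(preds))
  strict <- numeric(length(preds))
  for (i in seq_along(preds)) {
    if (is.na(top1[[i]])) next
    rs <- refs[[mention_ids[[i]]]]
    sim[[i]] <- max(wm[top1[[i]], rs])
    strict[[i]] <- as.numeric(top1[[i]] %in% rs)
  }
  records <- tibble::tibble(
    mention = mention_ids,
    predicted = top1,
    reference = vapply(refs[mention_ids], paste, character(1L), collapse = ","),
    similarity = sim,
    strict = strict
  )
  structure(
    list(
      semantic_score = mean(sim),
      strict_score = mean(strict),
      n_mentions = length(preds),
      n_no_vector = sum(is.na(top1)),
      records = records,
      cfg = cfg
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d mentions (%d without vector)\n  semantic score: %.4f\n  strict score:   %.4f\n",
    x$n_mentions, x$n_no_vector, x$semantic_score, x$strict_score
  ))
  invisible(x)
}

#' Expected semantic score of uniform-random concept assignment
#'
#' Monte-Carlo baseline: draws a uniformly random concept for every mention
#' `n_draws` times and averages the resulting semantic scores (strict scores
#' are returned too). Used to check that a trained pipeline carries signal.
#'
#' @param refs Named list: mention -> reference concept identifiers.
#' @param onto An [ontology()] object.
#' @param cfg A [similarity_config()].
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @return List with `semantic_score`, `strict_score`, `n_draws`.
#' @export
random_assignment_baseline <- function(refs, onto, cfg = similarity_config(),
                                       n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(onto, "ontology"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ref_concepts <- unique(unlist(refs, use.names = FALSE))
  wm <- .wang_matrix(onto, onto$concepts, ref_concepts, cfg)
  # per mention: similarity of every possible random pick to its best reference
  best_sim <- vapply(refs, function(rs) {
    apply(wm[, rs, drop = FALSE], 1L, max)
  }, numeric(length(onto$concepts)))
  strict_hit <- vapply(refs, function(rs) {
    as.numeric(onto$concepts %in% rs)
  }, numeric(length(onto$concepts)))
  n <- length(refs)
  sems <- numeric(n_draws)
  stricts <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    picks <- sample.int(length(onto$concepts), n, replace = TRUE)
    idx <- cbind(picks, seq_len(n))
    sems[[d]] <- mean(best_sim[idx])
    stricts[[d]] <- mean(strict_hit[idx])
  }
  list(semantic_score = mean(sems), strict_score = mean(stricts),
       n_draws = n_draws)
}

# shared plumbing for the sweep experiments: term vectors once, then
# (sso -> fit -> predict -> score) per grid point
.sweep_eval <- function(onto, train_pairs, eval_pairs, embeddings, cfg,
                        loss, make_sso) {
  tm <- pairs_to_matrix(train_pairs, embeddings)
  if (nrow(tm$x) == 0L) stop("no training pair has vector coverage")
  eval_mentions <- .eval_mentions(eval_pairs)
  refs <- eval_mentions$refs
  function(...) {
    sso <- make_sso(...)
    p <- fit_projection(tm$x, tm$concepts, sso, loss = loss)
    preds <- predict_mentions(p, sso, embeddings, eval_mentions$mentions, k = 1L)
    score_predictions(preds, refs, onto, cfg)
  }
}

# collapse evaluation pairs to one row per mention with a reference set
.eval_mentions <- function(eval_pairs) {
  ids <- eval_pairs$mention_id
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(eval_pairs)))
  first <- !duplicated(ids)
  mentions <- tibble::tibble(
    mention_id = ids[first],
    tokens = eval_pairs$tokens[first]
  )
  refs <- split(eval_pairs$concept_id, ids)[mentions$mention_id]
  list(mentions = mentions, refs = lapply(refs, unique))
}

#' Decay-factor sweep experiment
#'
#' For each decay factor in the grid: builds the decay concept space, fits
#' the projection on the training pairs, predicts the evaluation mentions and
#' scores them. The default grid runs from 0 to 1 in steps of 0.1 (11 rows),
#' spanning one-hot (w = 0) to binary ancestry (w = 1).
#'
#' @param onto An [ontology()] object.
#' @param train_pairs Training pairs (see [build_training_pairs()]).
#' @param eval_pairs Evaluation pairs with columns `mention_id`, `tokens`,
#'   `concept_id` (several rows per mention = several reference concepts).
#' @param embeddings Word embeddings for term composition.
#' @param grid Decay factors in \[0,1\].
#' @param cfg A [similarity_config()].
#' @param loss Projection loss, passed to [fit_projection()].
#' @return Tibble with columns `w`, `semantic_score`, `strict_score`.
#' @export
sweep_decay <- function(onto, train_pairs, eval_pairs, embeddings,
                        grid = seq(0, 1, by = 0.1),
                        cfg = similarity_config(),
                        loss = "least_squares") {
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  run <- .sweep_eval(onto, train_pairs, eval_pairs, embeddings, cfg, loss,
                     make_sso = function(w) build_decay_sso(onto, w))
  rows <- lapply(grid, function(w) {
    rep <- run(w)
    tibble::tibble(w = w, semantic_score = rep$semantic_score,
                   strict_score = rep$strict_score)
  })
  do.call(rbind, rows)
}

#' Dimensionality-reduction sweep experiment
#'
#' Starting from a decay concept space, reduces it to
#' `ceiling((1 - fraction) * dim)` dimensions for each requested reduction
#' fraction, retrains the projection and rescores. At fraction 0 with
#' `method = "svd"` the transform is orthogonal and cosine-preserving, so the
#' scores equal the unreduced run.
#'
#' @inheritParams sweep_decay
#' @param method Reduction method: `"pca"`, `"mds"` or `"svd"`.
#' @param fractions Reduction fractions in \[0,1).
#' @param w Decay factor of the base concept space (1 = ancestry).
#' @return Tibble with columns `fraction`, `target_dim`, `semantic_score`,
#'   `strict_score`.
#' @export
sweep_reduction <- function(onto, train_pairs, eval_pairs, embeddings,
                            method = c("pca", "mds", "svd"),
                            fractions = c(0, 0.3, 0.6, 0.9),
                            cfg = similarity_config(), w = 1,
                            loss = "least_squares") {
  method <- match.arg(method)
  if (any(fractions < 0 | fractions >= 1)) {
    stop("fractions must lie in [0, 1)")
  }
  base <- build_decay_sso(onto, w)
  d0 <- ncol(base$matrix)
  run <- .sweep_eval(
    onto, train_pairs, eval_pairs, embeddings, cfg, loss,
    make_sso = function(f) {
      reduce_dimensions(base, method, target_dim = ceiling((1 - f) * d0))
    }
  )
  rows <- lapply(fractions, function(f) {
    rep <- run(f)
    tibble::tibble(
      fraction = f, target_dim = as.integer(ceiling((1 - f) * d0)),
      semantic_score = rep$semantic_score, strict_score = rep$strict_score
    )
  })
  do.call(rbind, rows)
}

#' Write an evaluation report as TSV records plus a JSON summary
#'
#' @param report An `evaluation_report`.
#' @param path Base path: records go to `path` (TSV), the summary to
#'   `paste0(path, ".summary.json")`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  utils::write.table(report$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(
      semantic_score = report$semantic_score,
      strict_score = report$strict_score,
      n_mentions = report$n_mentions,
      n_no_vector = report$n_no_vector,
      contribution_factor = report$cfg$contribution_factor
    ),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
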