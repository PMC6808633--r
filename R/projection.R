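#' Fit the linear projection from term space to concept space
#'
#' Learns the linear map that carries composed term vectors (the corpus
#' space) onto the vectors of their associated concepts (the ontology space),
#' so that a projected term lands near its concept under cosine similarity.
#' Two losses are available:
#' \describe{
#'   \item{`least_squares`}{closed-form multivariate least squares of the
#'     (optionally unit-normalized) concept rows on the term vectors, via an
#'     SVD pseudo-inverse (handles rank deficiency and n < p). Deterministic,
#'     no tuning; the default.}
#'   \item{`cosine`}{direct ascent on the mean cosine between projected term
#'     vectors and their concept rows — the training objective itself.
#'     Initialised from the least-squares solution and refined with a fixed
#'     budget of Adam steps; the final mean cosine is recorded.}
#' }
#' Unit-normalizing the targets aligns the least-squares surrogate with the
#' cosine objective and is on by default.
#'
#' @param x Numeric matrix of term vectors, one row per training pair.
#' @param concepts Character vector (length `nrow(x)`) of associated concepts.
#' @param sso A [concept_space()] containing every concept in `concepts`.
#' @param loss `"least_squares"` or `"cosine"`.
#' @param normalize_targets Unit-normalize concept rows before fitting.
#' @param bias Include an intercept term.
#' @param seed Recorded in metadata (the fit is deterministic).
#' @param max_iter Adam steps for the cosine loss.
#' @param lr Adam learning rate for the cosine loss.
#' @return Object of class `trained_projection` with `map_matrix`
#'   (sso dim x ssc dim), `bias` (sso dim), and `training_meta`.
#' @export
fit_projection <- function(x, concepts, sso,
                           loss = c("least_squares", "cosine"),
                           normalize_targets = TRUE, bias = TRUE, seed = 1L,
                           max_iter = 300L, lr = 0.05) {
  loss <- match.arg(loss)
  stopifnot(inherits(sso, "concept_space"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("at least one training pair is required")
  if (length(concepts) != nrow(x)) stop("length(concepts) must equal nrow(x)")
  missing_c <- setdiff(unique(concepts), rownames(sso$matrix))
  if (length(missing_c) > 0L) {
    stop("concept(s) absent from the concept space: ",
         paste(missing_c, collapse = ", "))
  }
  nz <- rowSums(abs(x)) > 0
  n_rejected <- sum(!nz)
  if (n_rejected > 0L) {
    warning(n_rejected, " all-zero term vector(s) rejected from training")
    x <- x[nz, , drop = FALSE]
    concepts <- concepts[nz]
  }
  if (nrow(x) == 0L) stop("no usable training pair (all term vectors zero)")

  input_scale <- mean(sqrt(rowSums(x^2)))

  y <- sso$matrix[concepts, , drop = FALSE]
  if (normalize_targets) {
    nrm <- sqrt(rowSums(y^2))
    nrm[nrm == 0] <- 1
    y <- y / nrm
  }

  xa <- if (bias) cbind(1, x) else x
  b_all <- .pinv_solve(xa, y)          # (p[+1]) x d_sso coefficients
  if (bias) {
    b0 <- b_all[1L, ]
    m <- t(b_all[-1L, , drop = FALSE]) # d_sso x d_ssc
  } else {
    b0 <- numeric(ncol(y))
    m <- t(b_all)
  }

  dimnames(m) <- NULL
  names(b0) <- NULL

  final_cos <- .mean_cosine(m, b0, x, y)
  if (loss == "cosine") {
    fit <- .cosine_ascent(m, b0, x, y, max_iter = max_iter, lr = lr,
                          use_bias = bias)
    m <- fit$m
    b0 <- fit$b
    final_cos <- fit$mean_cosine
  }

  structure(
    list(
      map_matrix = m,
      bias = b0,
      training_meta = list(
        loss = loss, n_pairs = nrow(x), n_rejected = n_rejected,
        normalize_targets = normalize_targets, bias = bias, seed = seed,
        input_scale = input_scale,
        ssc_dim = ncol(x), sso_dim = ncol(sso$matrix),
        sso_method = sso$meta$method, final_mean_cosine = final_cos
      )
    ),
    class = "trained_projection"
  )
}

#' @export
print.trained_projection <- function(x, ...) {
  tm <- x$training_meta
  cat(sprintf(
    "<trained_projection> %d -> %d dims, loss=%s, %d pairs, mean cosine %.4f\n",
    tm$ssc_dim, tm$sso_dim, tm$loss, tm$n_pairs, tm$final_mean_cosine
  ))
  invisible(x)
}

# minimum-norm least squares via SVD pseudo-inverse
.pinv_solve <- function(a, y, tol = 1e-10) {
  sv <- svd(a)
  d <- sv$d
  pos <- d > tol * max(d)
  dinv <- ifelse(pos, 1 / d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% y))
}

.mean_cosine <- function(m, b, x, y) {
  u <- x %*% t(m) + matrix(b, nrow(x), length(b), byrow = TRUE)
  un <- sqrt(rowSums(u^2))
  yn <- sqrt(rowSums(y^2))
  ok <- un > 0 & yn > 0
  cs <- rowSums(u * y)[ok] / (un[ok] * yn[ok])
  if (!any(ok)) 0 else mean(c(cs, rep(0, sum(!ok))))
}

# fixed-budget Adam ascent on the mean cosine; keeps the best iterate
.cosine_ascent <- function(m, b, x, y, max_iter = 300L, lr = 0.05,
                           use_bias = TRUE, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  n <- nrow(x)
  yn <- sqrt(rowSums(y^2))
  yn[yn == 0] <- 1
  yh <- y / yn
  mm <- matrix(0, nrow(m), ncol(m)); vm <- mm
  mb <- numeric(length(b)); vb <- mb
  best <- list(m = m, b = b, mean_cosine = .mean_cosine(m, b, x, y))
  for (it in seq_len(max_iter)) {
    u <- x %*% t(m) + matrix(b, n, length(b), byrow = TRUE)
    un <- sqrt(rowSums(u^2))
    un[un < 1e-12] <- 1e-12
    uh <- u / un
    cs <- rowSums(uh * yh)
    # d(mean cos)/du_i = (yh_i - cs_i * uh_i) / (n * |u_i|)
    g_u <- (yh - cs * uh) / (n * un)
    g_m <- t(g_u) %*% x
    g_b <- colSums(g_u)
    mm <- beta1 * mm + (1 - beta1) * g_m
    vm <- beta2 * vm + (1 - beta2) * g_m^2
    m <- m + lr * (mm / (1 - beta1^it)) / (sqrt(vm / (1 - beta2^it)) + eps)
    if (use_bias) {
      mb <- beta1 * mb + (1 - beta1) * g_b
      vb <- beta2 * vb + (1 - beta2) * g_b^2
      b <- b + lr * (mb / (1 - beta1^it)) / (sqrt(vb / (1 - beta2^it)) + eps)
    }
    mc <- .mean_cosine(m, b, x, y)
    if (mc > best$mean_cosine) best <- list(m = m, b = b, mean_cosine = mc)
  }
  best
}

#' Project a term vector into the concept space
#'
#' @param p A [fit_projection()] result.
#' @param x Numeric vector of the trained term-space dimension.
#' @return Numeric vector of the concept-space dimension
#'   (`map_matrix %*% x + bias`).
#' @export
project <- function(p, x) {
  stopifnot(inherits(p, "trained_projection"))
  if (length(x) != ncol(p$map_matrix)) {
    stop("term vector has dimension ", length(x),
         " but the projection was trained on dimension ", ncol(p$map_matrix))
  }
  drop(p$map_matrix %*% x + p$bias)
}

#' Predict concepts for a term vector by cosine nearest neighbour
#'
#' Projects the term vector into the concept space and ranks all concepts by
#' cosine similarity to the projected vector. The query is rescaled to the
#' mean norm of the training inputs before projection, so the ranked list is
#' invariant to positive rescaling of the query (with a bias term the raw
#' affine image of `s * x` would change direction with `s`) while the bias
#' still acts at the magnitude it was fitted for. Ties are broken by
#' lexicographic concept identifier. An all-zero projected vector (e.g. an
#' out-of-vocabulary mention under a zero map) yields `status = "no_vector"`
#' and an empty ranking rather than an arbitrary prediction.
#'
#' @param p A [fit_projection()] result.
#' @param sso The [concept_space()] to rank against.
#' @param x Term vector (or `NULL`/all-zero for a no-vector mention).
#' @param k Number of ranked concepts to return (`k <=` number of concepts).
#' @param mention Optional mention identifier carried into the result.
#' @return Object of class `concept_prediction`: `mention`, `status`
#'   (`"ok"` or `"no_vector"`), `ranking` (data frame `concept`, `score`,
#'   `k` rows, scores non-increasing).
#' @export
predict_concepts <- function(p, sso, x, k = 1L, mention = NA_character_) {
  stopifnot(inherits(p, "trained_projection"), inherits(sso, "concept_space"))
  n <- nrow(sso$matrix)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  if (ncol(sso$matrix) != nrow(p$map_matrix)) {
    stop("concept space dimension ", ncol(sso$matrix),
         " does not match projection output dimension ", nrow(p$map_matrix))
  }
  if (is.null(x) || all(x == 0)) {
    return(structure(
      list(mention = mention, status = "no_vector",
           ranking = data.frame(concept = character(), score = numeric())),
      class = "concept_prediction"
    ))
  }
  scale0 <- p$training_meta$input_scale
  if (is.null(scale0) || !is.finite(scale0) || scale0 <= 0) scale0 <- 1
  y <- project(p, x * (scale0 / sqrt(sum(x^2))))
  yn <- sqrt(sum(y^2))
  if (yn == 0) {
    return(structure(
      list(mention = mention, status = "no_vector",
           ranking = data.frame(concept = character(), score = numeric())),
      class = "concept_prediction"
    ))
  }
  rn <- sqrt(rowSums(sso$matrix^2))
  score <- as.numeric(sso$matrix %*% y) / (pmax(rn, 1e-300) * yn)
  score[rn == 0] <- 0
  ord <- order(-score, rownames(sso$matrix))
  top <- ord[seq_len(k)]
  structure(
    list(mention = mention, status = "ok",
         ranking = data.frame(concept = rownames(sso$matrix)[top],
                              score = score[top])),
    class = "concept_prediction"
  )
}

#' @export
print.concept_prediction <- function(x, ...) {
  if (x$status == "no_vector") {
    cat("<concept_prediction> no vector (all tokens out of vocabulary)\n")
  } else {
    cat(sprintf("<concept_prediction> top: %s (cosine %.4f)\n",
                x$ranking$concept[[1L]], x$ranking$score[[1L]]))
  }
  invisible(x)
}

#' Predict concepts for a set of mentions
#'
#' Composes a term vector per mention (mean of its token vectors), predicts
#' with [predict_concepts()], and flags mentions whose every token is out of
#' vocabulary as `no_vector`.
#'
#' @param p A [fit_projection()] result.
#' @param sso The [concept_space()] to rank against.
#' @param emb Word embeddings for term composition.
#' @param mentions Tibble/data frame with columns `mention_id` and `tokens`
#'   (list of character vectors) — or `surface`, which is tokenized.
#' @param k Ranking depth per mention.
#' @return List of `concept_prediction`, one per row of `mentions`.
#' @export
predict_mentions <- function(p, sso, emb, mentions, k = 1L) {
  toks <- mentions$tokens
  if (is.null(toks)) toks <- lapply(mentions$surface, tokenize)
  lapply(seq_len(nrow(mentions)), function(i) {
    tv <- term_vector(emb, toks[[i]])
    x <- if (tv$coverage > 0) tv$vector else NULL
    predict_concepts(p, sso, x, k = k, mention = mentions$mention_id[[i]])
  })
}

#' Write a trained projection as TSV + JSON meta sidecar
#'
#' One row per concept-space dimension: the first column holds the bias
#' vector, the remaining columns the map matrix. Metadata goes to
#' `paste0(path, ".meta.json")`.
#'
#' @param p A [fit_projection()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(p, path) {
  stopifnot(inherits(p, "trained_projection"))
  m <- cbind(p$bias, p$map_matrix)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(p$training_meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a projection written by [write_projection()]
#'
#' @param path TSV path with JSON meta sidecar.
#' @return A `trained_projection`.
#' @export
read_projection <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  colnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(
    list(bias = m[, 1L], map_matrix = m[, -1L, drop = FALSE],
         training_meta = meta),
    class = "trained_projection"
  )
}
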