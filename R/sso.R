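#' Concept vector space constructor
#'
#' Thin container for one vector per ontology concept. Rows are ordered and
#' named by concept identifier (lexicographic, fixed by the ontology), and
#' `meta` records how the space was built so downstream reports can state it.
#'
#' @param matrix Numeric matrix, one row per concept, rownames = concept ids.
#' @param meta Named list describing the construction (at least `method`).
#' @return Object of class `concept_space`.
#' @export
concept_space <- function(matrix, meta) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  structure(list(matrix = matrix, meta = meta), class = "concept_space")
}

#' @export
print.concept_space <- function(x, ...) {
  cat(sprintf(
    "<concept_space> %d concepts x %d dims, method=%s\n",
    nrow(x$matrix), ncol(x$matrix), x$meta$method
  ))
  invisible(x)
}

#' Build a decay-weighted ancestor concept space
#'
#' Each concept is represented in a space with one dimension per concept.
#' The entry for ancestor `a` of concept `c` is `w^d`, where `d` is the
#' minimum is-a edge distance from `c` to `a` (0 for the concept itself,
#' 1 for a direct parent) and `w` is the decay factor in \[0,1\]. All
#' non-ancestor entries are 0. The convention `0^0 = 1` applies, so:
#' `w = 1` reproduces the binary ancestry representation and `w = 0` the
#' one-hot representation.
#'
#' @param onto An [ontology()] object.
#' @param w Decay factor in \[0,1\].
#' @return A [concept_space()] of dimension `|concepts|`.
#' @export
build_decay_sso <- function(onto, w) {
  stopifnot(inherits(onto, "ontology"))
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("decay factor w must be a single number in [0, 1], got ", w)
  }
  n <- length(onto$concepts)
  m <- matrix(0, n, n, dimnames = list(onto$concepts, onto$concepts))
  for (c_id in onto$concepts) {
    d <- ancestor_distances(onto, c_id)
    v <- ifelse(d == 0L, 1, w^d)  # 0^0 := 1
    m[c_id, names(d)] <- v
  }
  method <- if (w == 1) "ancestry" else if (w == 0) "onehot" else "decay"
  concept_space(m, meta = list(method = method, decay = w))
}

#' Configuration for graph-walk concept embeddings
#'
#' Hyperparameters of the node2vec-style builder: biased second-order random
#' walks over the (undirected) is-a graph, fed to a skip-gram objective with
#' negative sampling.
#'
#' @param dimension Embedding dimension.
#' @param walk_length Steps per walk.
#' @param walks_per_node Walks started from each concept.
#' @param p Return parameter (likelihood of revisiting the previous node is
#'   proportional to `1/p`).
#' @param q In-out parameter (moving away from the previous node's
#'   neighbourhood is proportional to `1/q`).
#' @param window Skip-gram context window.
#' @param epochs Training epochs over the walk corpus.
#' @param seed Integer seed; fixed seed + single worker gives identical output.
#' @param include_extra_edges Also walk over non-is-a `extra_edges`.
#' @return A list of class `graph_embed_config`.
#' @export
graph_embed_config <- function(dimension = 64L, walk_length = 10L,
                               walks_per_node = 20L, p = 1, q = 1,
                               window = 5L, epochs = 5L, seed = 1L,
                               include_extra_edges = FALSE) {
  stopifnot(dimension >= 1L, walk_length >= 1L, walks_per_node >= 1L,
            p > 0, q > 0, window >= 1L, epochs >= 1L)
  structure(
    list(
      dimension = as.integer(dimension), walk_length = as.integer(walk_length),
      walks_per_node = as.integer(walks_per_node), p = p, q = q,
      window = as.integer(window), epochs = as.integer(epochs),
      seed = as.integer(seed), include_extra_edges = include_extra_edges
    ),
    class = "graph_embed_config"
  )
}

# biased second-order walks on an adjacency list (node indices)
.node2vec_walks <- function(adj, cfg) {
  n <- length(adj)
  walks <- vector("list", n * cfg$walks_per_node)
  k <- 0L
  for (rep in seq_len(cfg$walks_per_node)) {
    for (start in seq_len(n)) {
      walk <- start
      if (length(adj[[start]]) > 0L) {
        prev <- NA_integer_
        cur <- start
        for (step in seq_len(cfg$walk_length - 1L)) {
          nbrs <- adj[[cur]]
          if (length(nbrs) == 0L) break
          if (is.na(prev)) {
            nxt <- nbrs[[sample.int(length(nbrs), 1L)]]
          } else {
            wts <- vapply(nbrs, function(x) {
              if (x == prev) 1 / cfg$p
              else if (x %in% adj[[prev]]) 1
              else 1 / cfg$q
            }, numeric(1L))
            nxt <- nbrs[[sample.int(length(nbrs), 1L, prob = wts)]]
          }
          walk <- c(walk, nxt)
          prev <- cur
          cur <- nxt
        }
      }
      k <- k + 1L
      walks[[k]] <- walk
    }
  }
  walks
}

#' Build a graph-walk (node2vec-style) concept space
#'
#' Runs biased second-order random walks over the is-a graph treated as
#' undirected (optionally including non-is-a edges) and trains skip-gram
#' embeddings on the walk corpus. Isolated concepts still receive a vector
#' (their walks have length 1 and their vector stays near its random
#' initialisation).
#'
#' @param onto An [ontology()] object.
#' @param cfg A [graph_embed_config()].
#' @return A [concept_space()] with `cfg$dimension` columns.
#' @export
build_node2vec_sso <- function(onto, cfg = graph_embed_config()) {
  stopifnot(inherits(onto, "ontology"), inherits(cfg, "graph_embed_config"))
  concepts <- onto$concepts
  n <- length(concepts)
  idx <- stats::setNames(seq_len(n), concepts)
  adj <- vector("list", n)
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (c_id in concepts) {
    for (p in onto$parents[[c_id]]) add_edge(idx[[c_id]], idx[[p]])
  }
  if (isTRUE(cfg$include_extra_edges) && !is.null(onto$extra_edges)) {
    for (i in seq_len(nrow(onto$extra_edges))) {
      from <- onto$extra_edges$from[[i]]
      to <- onto$extra_edges$to[[i]]
      if (from %in% concepts && to %in% concepts) add_edge(idx[[from]], idx[[to]])
    }
  }
  adj <- lapply(adj, unique)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  walks <- .node2vec_walks(adj, cfg)

  fit <- sgns_train_cpp(
    sentences = lapply(walks, function(w) as.integer(w - 1L)),
    vocab_size = n,
    counts = as.numeric(tabulate(unlist(walks), nbins = n) + 1L),
    dim = cfg$dimension, window = cfg$window, negative = 5L,
    epochs = cfg$epochs, alpha0 = 0.05, cbow = FALSE,
    subword = list(), n_buckets = 0L, seed = cfg$seed
  )
  m <- fit$words
  rownames(m) <- concepts
  concept_space(m, meta = list(
    method = "node2vec", dimension = cfg$dimension,
    walk_length = cfg$walk_length, walks_per_node = cfg$walks_per_node,
    p = cfg$p, q = cfg$q, window = cfg$window, epochs = cfg$epochs,
    seed = cfg$seed
  ))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reduce the dimension of a concept space
#'
#' Supported methods: `pca` (centered principal components via [stats::prcomp]),
#' `svd` (uncentered truncated singular value decomposition), `mds` (classical
#' metric multidimensional scaling of Euclidean row distances via
#' [stats::cmdscale]; deterministic). t-SNE is deliberately refused: it does
#' not scale to the target dimensionalities this space requires and is meant
#' for 2D/3D visualisation only.
#'
#' @param sso A [concept_space()].
#' @param method One of `"pca"`, `"mds"`, `"svd"`.
#' @param target_dim Number of output dimensions, `1 <= target_dim <= ncol`.
#' @param seed Recorded in meta; the implemented methods are deterministic.
#' @return A [concept_space()] with `target_dim` columns; `meta` records the
#'   method, target dimension and the reduction fraction
#'   `1 - target_dim/original_dim`.
#' @export
reduce_dimensions <- function(sso, method = c("pca", "mds", "svd"),
                              target_dim, seed = 1L) {
  stopifnot(inherits(sso, "concept_space"))
  method_in <- as.character(method)[[1L]]
  if (identical(method_in, "tsne")) {
    stop("t-SNE reduction is not supported: it is intended for 2D/3D ",
         "visualisation and does not scale to the embedding dimensions ",
         "needed here; use pca, mds or svd")
  }
  method <- match.arg(method)
  d0 <- ncol(sso$matrix)
  if (!is.numeric(target_dim) || target_dim < 1L || target_dim > d0) {
    stop("target_dim must be in [1, ", d0, "], got ", target_dim)
  }
  target_dim <- as.integer(target_dim)
  x <- sso$matrix
  red <- switch(method,
    pca = {
      pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = target_dim)
      pr$x[, seq_len(target_dim), drop = FALSE]
    },
    svd = {
      sv <- svd(x, nu = target_dim, nv = 0L)
      sv$u %*% diag(sv$d[seq_len(target_dim)], nrow = target_dim)
    },
    mds = {
      stats::cmdscale(stats::dist(x), k = target_dim)
    }
  )
  red <- as.matrix(red)
  # cmdscale can return fewer columns than requested when the configuration
  # is degenerate; pad with zeros so the contract on ncol holds
  if (ncol(red) < target_dim) {
    red <- cbind(red, matrix(0, nrow(red), target_dim - ncol(red)))
  }
  rownames(red) <- rownames(x)
  colnames(red) <- NULL
  concept_space(red, meta = list(
    method = "reduced", base_method = sso$meta$method,
    reduction = method, target_dim = target_dim,
    reduction_fraction = 1 - target_dim / d0, seed = seed
  ))
}

#' Write a concept space as TSV + JSON meta sidecar
#'
#' The matrix goes to `path` as `concept_id<TAB>v1<TAB>v2...` (one row per
#' concept, full precision) and `meta` to `paste0(path, ".meta.json")`.
#'
#' @param sso A [concept_space()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_concept_space <- function(sso, path) {
  stopifnot(inherits(sso, "concept_space"))
  df <- data.frame(concept_id = rownames(sso$matrix), sso$matrix,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sso$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a concept space written by [write_concept_space()]
#'
#' @param path TSV path; `paste0(path, ".meta.json")` must exist alongside.
#' @return A [concept_space()].
#' @export
read_concept_space <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  colnames(m) <- NULL
  storage.mode(m) <- "double"
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  # decay-family spaces have one dimension per concept, in concept order
  if (isTRUE(meta$method %in% c("ancestry", "decay", "onehot")) &&
      ncol(m) == nrow(m)) {
    colnames(m) <- rownames(m)
  }
  concept_space(m, meta = meta)
}
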