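#' Tokenize text for embedding training and term lookup
#'
#' Lowercases and splits on every non-alphanumeric boundary (any Unicode
#' punctuation or whitespace); digits are preserved and empty tokens dropped.
#'
#' @param text A character scalar (or vector; tokens are concatenated per
#'   element and a list is returned for length > 1).
#' @return Character vector of tokens (a list of such for vector input).
#' @export
tokenize <- function(text) {
  one <- function(s) {
    if (is.na(s) || s == "") return(character())
    toks <- strsplit(tolower(s), "[^\\p{L}\\p{N}]+", perl = TRUE)[[1L]]
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

# hashed character n-grams with word boundary markers, as in subword models
.ngram_buckets <- function(word, nmin = 3L, nmax = 6L, n_buckets = 32768L) {
  w <- paste0("<", word, ">")
  chars <- utf8ToInt(w)
  nc <- length(chars)
  out <- integer()
  for (n in nmin:nmax) {
    if (nc < n) break
    for (i in seq_len(nc - n + 1L)) {
      h <- 0
      for (b in chars[i:(i + n - 1L)]) {
        h <- (h * 131 + (b %% 1024)) %% 1048576
      }
      out <- c(out, h %% n_buckets)
    }
  }
  unique(out)
}

#' Train word embeddings on a tokenized corpus
#'
#' A compiled single-worker word2vec-style trainer with negative sampling.
#' Modes: `skipgram`, `cbow`, and `subword` (skip-gram whose input
#' representation is the mean of the word vector and its hashed character
#' 3--6-gram vectors, so unseen words can be composed from their n-grams at
#' query time). Fixed seed + single worker give reproducible vectors.
#'
#' @param corpus List of character vectors (one token vector per sentence).
#' @param dimension Embedding dimension.
#' @param mode One of `"skipgram"`, `"cbow"`, `"subword"`.
#' @param window Context window size.
#' @param min_count Minimum corpus frequency for a word to get a vector.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @param negative Number of negative samples per update.
#' @param alpha Initial learning rate (linearly decayed).
#' @param n_buckets Number of n-gram hash buckets (subword mode).
#' @return An object of class `word_embeddings` with fields `matrix`
#'   (vocab x dimension, rownames = words), `dimension`, `mode`,
#'   `oov_policy` (`"subword"` for subword mode, `"skip"` otherwise), and
#'   for subword mode the bucket matrix used to compose unseen words.
#' @export
train_word_embeddings <- function(corpus, dimension = 50L,
                                  mode = c("skipgram", "cbow", "subword"),
                                  window = 5L, min_count = 1L, epochs = 10L,
                                  seed = 1L, negative = 5L, alpha = 0.05,
                                  n_buckets = 32768L) {
  mode <- match.arg(mode)
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop("corpus must be a non-empty list of token vectors")
  }
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) == 0L) stop("corpus contains no tokens")
  freq <- table(toks)
  vocab <- sort(names(freq)[freq >= min_count])
  if (length(vocab) == 0L) stop("no word reaches min_count = ", min_count)
  idx <- stats::setNames(seq_along(vocab), vocab)
  counts <- as.numeric(freq[vocab])

  sentences <- lapply(corpus, function(s) {
    ids <- idx[s[s %in% vocab]]
    as.integer(unname(ids) - 1L)
  })
  sentences <- sentences[vapply(sentences, length, 1L) > 0L]
  if (length(sentences) == 0L) stop("corpus empty after vocabulary filtering")

  use_sub <- mode == "subword"
  subword <- if (use_sub) {
    lapply(vocab, function(w) as.integer(.ngram_buckets(w, n_buckets = n_buckets)))
  } else list()

  fit <- sgns_train_cpp(
    sentences = sentences, vocab_size = length(vocab), counts = counts,
    dim = as.integer(dimension), window = as.integer(window),
    negative = as.integer(negative), epochs = as.integer(epochs),
    alpha0 = alpha, cbow = (mode == "cbow"),
    subword = subword, n_buckets = if (use_sub) as.integer(n_buckets) else 0L,
    seed = as.integer(seed)
  )

  if (use_sub) {
    # store each in-vocabulary word as its composed representation so that a
    # query of a trained word returns exactly the vector used in training
    m <- matrix(0, length(vocab), dimension)
    for (i in seq_along(vocab)) {
      rows <- rbind(fit$words[i, ], fit$buckets[subword[[i]] + 1L, , drop = FALSE])
      m[i, ] <- colMeans(rows)
    }
  } else {
    m <- fit$words
  }
  rownames(m) <- vocab
  structure(
    list(
      matrix = m, dimension = as.integer(dimension), mode = mode,
      oov_policy = if (use_sub) "subword" else "skip",
      buckets = if (use_sub) fit$buckets else NULL,
      n_buckets = if (use_sub) as.integer(n_buckets) else NULL,
      meta = list(window = window, min_count = min_count, epochs = epochs,
                  seed = seed, negative = negative, alpha = alpha)
    ),
    class = "word_embeddings"
  )
}

#' @export
print.word_embeddings <- function(x, ...) {
  cat(sprintf("<word_embeddings> %d words x %d dims, mode=%s, oov_policy=%s\n",
              nrow(x$matrix), x$dimension, x$mode, x$oov_policy))
  invisible(x)
}

#' Look up the vector of a single word
#'
#' In-vocabulary words return their stored vector. Out-of-vocabulary words
#' return `NULL` under `oov_policy = "skip"`, and the mean of their hashed
#' character n-gram vectors under `oov_policy = "subword"` (a finite vector
#' for any non-empty word).
#'
#' @param emb A [train_word_embeddings()] result.
#' @param word A single word (will be lowercased).
#' @return Numeric vector of length `emb$dimension`, or `NULL` when the word
#'   has no representation.
#' @export
word_vector <- function(emb, word) {
  stopifnot(inherits(emb, "word_embeddings"))
  word <- tolower(word)
  i <- match(word, rownames(emb$matrix))
  if (!is.na(i)) return(emb$matrix[i, ])
  if (emb$oov_policy == "subword" && nzchar(word)) {
    b <- .ngram_buckets(word, n_buckets = emb$n_buckets)
    if (length(b) > 0L) return(colMeans(emb$buckets[b + 1L, , drop = FALSE]))
  }
  NULL
}

#' Compose a term vector from its tokens
#'
#' Multiword terms are composed as the unweighted arithmetic mean of the
#' available token vectors; tokens without a vector are skipped and reported
#' through the coverage fraction. A term whose every token is unrepresentable
#' yields the zero vector with coverage 0 — callers must treat such terms as
#' unpredictable rather than feed the zero vector onward silently.
#'
#' @param emb A [train_word_embeddings()] result (or compatible object).
#' @param tokens Non-empty character vector of tokens.
#' @return List with `vector` (length `emb$dimension`) and `coverage`
#'   (fraction of tokens that had vectors, in \[0,1\]).
#' @export
term_vector <- function(emb, tokens) {
  if (length(tokens) == 0L) stop("tokens must be non-empty")
  vecs <- lapply(tokens, function(t) word_vector(emb, t))
  have <- !vapply(vecs, is.null, logical(1L))
  if (!any(have)) {
    return(list(vector = numeric(emb$dimension), coverage = 0))
  }
  m <- do.call(rbind, vecs[have])
  list(vector = colMeans(m), coverage = mean(have))
}

#' Write word embeddings in word2vec text format
#'
#' First line `"<vocab_size> <dimension>"`, then one `"word v1 v2 ..."` line
#' per word.
#'
#' @param emb A `word_embeddings` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(emb, path) {
  stopifnot(inherits(emb, "word_embeddings"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$matrix), emb$dimension), con)
  for (i in seq_len(nrow(emb$matrix))) {
    writeLines(paste(c(rownames(emb$matrix)[i],
                       format(emb$matrix[i, ], digits = 17, scientific = FALSE,
                              trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read word vectors in word2vec text format
#'
#' @param path Path to a text file whose first line is
#'   `"<vocab_size> <dimension>"`.
#' @return A `word_embeddings` object with `mode = "pretrained"` and
#'   `oov_policy = "skip"`.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  if (length(hdr) != 2L || any(is.na(hdr))) {
    stop("malformed word2vec header: ", lines[[1L]])
  }
  n <- hdr[[1L]]
  d <- hdr[[2L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != n) stop("header declares ", n, " words, found ", length(body))
  words <- character(n)
  m <- matrix(0, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(body[[i]], "\\s+")[[1L]]
    if (length(parts) != d + 1L) {
      stop("malformed vector line ", i + 1L, ": expected ", d, " values")
    }
    words[[i]] <- parts[[1L]]
    m[i, ] <- as.numeric(parts[-1L])
  }
  rownames(m) <- words
  structure(
    list(matrix = m, dimension = d, mode = "pretrained", oov_policy = "skip",
         buckets = NULL, n_buckets = NULL, meta = list(source = path)),
    class = "word_embeddings"
  )
}
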