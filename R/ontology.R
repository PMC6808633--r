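#' Construct an ontology object
#'
#' An `ontology` is a validated is-a DAG over a set of concept identifiers,
#' with a preferred label and optional synonyms per concept. Concepts are kept
#' in lexicographic identifier order, which fixes the dimension order of every
#' concept vector space built from the ontology.
#'
#' @param labels Named character vector: concept identifier -> preferred name.
#' @param parents Named list: concept identifier -> character vector of direct
#'   is-a parents (may be empty for roots). Names must cover all concepts.
#' @param synonyms Optional named list: concept identifier -> character vector
#'   of synonym strings.
#' @param extra_edges Optional data frame with columns `from`, `to`, `rel`
#'   holding non-is-a relationships (e.g. `sameAs`). These are ignored by
#'   ancestry and decay construction but may be included in graph embeddings.
#' @return An object of class `ontology` with fields `concepts`, `labels`,
#'   `synonyms`, `parents`, `children`, `roots`, `extra_edges`.
#' @export
ontology <- function(labels, parents, synonyms = NULL, extra_edges = NULL) {
  concepts <- sort(names(labels))
  if (length(concepts) == 0L) stop("ontology must contain at least one concept")
  if (anyDuplicated(concepts)) stop("duplicate concept identifiers")
  parents <- parents[concepts]
  names(parents) <- concepts
  parents <- lapply(parents, function(p) unique(as.character(p)))
  bad <- setdiff(unlist(parents, use.names = FALSE), concepts)
  if (length(bad) > 0L) {
    stop("parent(s) not present in the ontology: ", paste(bad, collapse = ", "))
  }
  cyc <- .find_cycle(concepts, parents)
  if (!is.null(cyc)) {
    stop("is-a relation contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  children <- stats::setNames(vector("list", length(concepts)), concepts)
  for (c_id in concepts) {
    for (p in parents[[c_id]]) children[[p]] <- c(children[[p]], c_id)
  }
  roots <- concepts[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0L) stop("ontology has no root concept")
  syn <- stats::setNames(rep(list(character()), length(concepts)), concepts)
  if (!is.null(synonyms)) {
    for (c_id in intersect(names(synonyms), concepts)) {
      syn[[c_id]] <- as.character(synonyms[[c_id]])
    }
  }
  structure(
    list(
      concepts = concepts,
      labels = labels[concepts],
      synonyms = syn,
      parents = parents,
      children = children,
      roots = roots,
      extra_edges = extra_edges
    ),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, 1L))
  cat(sprintf(
    "<ontology> %d concepts, %d is-a edges, %d root(s)\n",
    length(x$concepts), n_edges, length(x$roots)
  ))
  invisible(x)
}

# Kahn topological sort on the child->parent relation; returns one cycle
# (as a concept path) if the graph is not a DAG, NULL otherwise.
.find_cycle <- function(concepts, parents) {
  indeg <- stats::setNames(vapply(parents, length, 1L), concepts)
  children <- stats::setNames(vector("list", length(concepts)), concepts)
  for (c_id in concepts) {
    for (p in parents[[c_id]]) children[[p]] <- c(children[[p]], c_id)
  }
  queue <- concepts[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(concepts)) return(NULL)
  # walk parent edges inside the residual subgraph until a repeat
  residual <- names(indeg)[indeg > 0L]
  path <- residual[[1L]]
  repeat {
    nxt <- intersect(parents[[path[[length(path)]]]], residual)[[1L]]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas (`id:`, `name:`, `synonym:`, `is_a:`,
#' `relationship:`, `is_obsolete:` lines). Obsolete terms are skipped;
#' non-is-a relationships are retained as `extra_edges`. The result is
#' validated (single definition per id, acyclic is-a graph, parents resolvable).
#'
#' @param path Path to an OBO flat file.
#' @return An [ontology()] object.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  labels <- character()
  parents <- list()
  synonyms <- list()
  extra <- list()
  cur <- NULL
  in_term <- FALSE

  flush_term <- function() {
    if (is.null(cur) || isTRUE(cur$obsolete)) return(invisible())
    if (is.null(cur$id)) {
      stop(sprintf("OBO parse error near line %d: [Term] stanza without id", cur$line))
    }
    if (is.null(cur$name)) {
      stop(sprintf("OBO parse error near line %d: term %s has no name", cur$line, cur$id))
    }
    labels[[cur$id]] <<- cur$name
    parents[[cur$id]] <<- cur$parents
    synonyms[[cur$id]] <<- cur$synonyms
    if (length(cur$extra) > 0L) extra[[length(extra) + 1L]] <<- cur$extra
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])  # strip trailing comments
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "[")) {
      flush_term()
      cur <- NULL
      if (line == "[Term]") {
        in_term <- TRUE
        cur <- list(
          id = NULL, name = NULL, parents = character(),
          synonyms = character(), extra = NULL, obsolete = FALSE, line = i
        )
      } else {
        in_term <- FALSE
      }
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(m) == 0L) {
      stop(sprintf("OBO parse error at line %d: %s", i, lines[[i]]))
    }
    key <- m[[2L]]
    val <- trimws(m[[3L]])
    if (key == "id") {
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, strsplit(val, "\\s+")[[1L]][[1L]])
    } else if (key == "synonym") {
      sm <- regmatches(val, regexec("^\"(.*)\"", val))[[1L]]
      if (length(sm) == 0L) {
        stop(sprintf("OBO parse error at line %d: malformed synonym", i))
      }
      cur$synonyms <- c(cur$synonyms, sm[[2L]])
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) < 2L) {
        stop(sprintf("OBO parse error at line %d: malformed relationship", i))
      }
      cur$extra <- rbind(
        cur$extra,
        data.frame(from = cur$id, to = parts[[2L]], rel = parts[[1L]])
      )
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
    # other keys (def:, comment:, xref:, ...) are ignored
  }
  flush_term()
  extra_edges <- if (length(extra) > 0L) do.call(rbind, extra) else NULL
  ontology(
    labels = unlist(labels),
    parents = parents,
    synonyms = synonyms,
    extra_edges = extra_edges
  )
}

#' Write an ontology as an OBO 1.2 flat file
#'
#' Emits one `[Term]` stanza per concept (id, name, synonyms as EXACT,
#' is_a edges), in lexicographic id order, so `read_obo(write_obo(x))`
#' round-trips concepts, labels, synonyms and edges.
#'
#' @param onto An [ontology()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  out <- c("format-version: 1.2", "")
  for (c_id in onto$concepts) {
    out <- c(out, "[Term]", paste0("id: ", c_id), paste0("name: ", onto$labels[[c_id]]))
    for (s in onto$synonyms[[c_id]]) {
      out <- c(out, sprintf("synonym: \"%s\" EXACT []", s))
    }
    for (p in sort(onto$parents[[c_id]])) {
      out <- c(out, sprintf("is_a: %s ! %s", p, onto$labels[[p]]))
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Ancestors of a concept (reflexive-transitive is-a closure)
#'
#' @param onto An [ontology()] object.
#' @param concept A concept identifier present in `onto`.
#' @return Character vector containing `concept` and every concept reachable
#'   from it along parent edges.
#' @export
ancestors <- function(onto, concept) {
  stopifnot(inherits(onto, "ontology"))
  if (!concept %in% onto$concepts) stop("unknown concept: ", concept)
  seen <- concept
  frontier <- concept
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(onto$parents[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Minimum edge distance from a concept to one of its ancestors
#'
#' The distance is the number of is-a edges on the shortest directed path:
#' 0 for the concept itself, 1 for a direct parent. With multiple inheritance
#' the minimum over all paths is taken.
#'
#' @inheritParams ancestors
#' @param ancestor A concept in `ancestors(onto, concept)`.
#' @return Non-negative integer edge count.
#' @export
min_edge_distance <- function(onto, concept, ancestor) {
  d <- ancestor_distances(onto, concept)
  if (!ancestor %in% names(d)) {
    if (!ancestor %in% onto$concepts) stop("unknown concept: ", ancestor)
    stop(ancestor, " is not an ancestor of ", concept)
  }
  d[[ancestor]]
}

#' Breadth-first distances from a concept to all its ancestors
#'
#' @inheritParams ancestors
#' @return Named integer vector: ancestor -> minimum edge distance, including
#'   the concept itself at distance 0.
#' @export
ancestor_distances <- function(onto, concept) {
  stopifnot(inherits(onto, "ontology"))
  if (!concept %in% onto$concepts) stop("unknown concept: ", concept)
  dist <- stats::setNames(0L, concept)
  frontier <- concept
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(onto$parents[frontier], use.names = FALSE)), names(dist))
    if (length(nxt) > 0L) {
      dist[nxt] <- d
    }
    frontier <- nxt
  }
  dist
}
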