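#' Read BioNLP-ST standoff annotations (.a1 entities, .a2 normalizations)
#'
#' `.a1` entity lines have the form
#' `Tn<TAB>Type start end[;start end...]<TAB>surface` with 0-based half-open
#' character offsets (a newline counts as one character); discontinuous
#' mentions carry several `start end` fragments. `.a2` normalization lines
#' have the form `Nn<TAB>Resource Annotation:Tn Referent:ID`. Offsets are
#' kept verbatim. A missing `.a2` yields empty normalizations.
#'
#' @param a1_path Path to the `.a1` file.
#' @param a2_path Optional path to the `.a2` file.
#' @return List with `mentions` (tibble `entity_id`, `type`, `spans` — list
#'   of 2-column start/end matrices — and `surface`) and `normalizations`
#'   (tibble `norm_id`, `entity_id`, `resource`, `referent`).
#' @export
read_standoff <- function(a1_path, a2_path = NULL) {
  if (!file.exists(a1_path)) stop("no such file: ", a1_path)
  lines <- readLines(a1_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  ent <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L || !grepl("^T[0-9]+$", parts[[1L]])) {
      stop(sprintf("%s:%d: malformed entity line: %s", a1_path, i, lines[[i]]))
    }
    ta <- strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]]
    type <- ta[[1L]]
    frag <- strsplit(paste(ta[-1L], collapse = " "), ";", fixed = TRUE)[[1L]]
    spans <- t(vapply(frag, function(f) {
      se <- suppressWarnings(as.integer(strsplit(trimws(f), " ")[[1L]]))
      if (length(se) != 2L || anyNA(se) || se[[1L]] >= se[[2L]]) {
        stop(sprintf("%s:%d: malformed span \"%s\"", a1_path, i, f))
      }
      se
    }, integer(2L)))
    dimnames(spans) <- list(NULL, c("start", "end"))
    ent[[length(ent) + 1L]] <- list(
      entity_id = parts[[1L]], type = type, spans = spans,
      surface = parts[[3L]]
    )
  }
  mentions <- tibble::tibble(
    entity_id = vapply(ent, `[[`, character(1L), "entity_id"),
    type = vapply(ent, `[[`, character(1L), "type"),
    spans = lapply(ent, `[[`, "spans"),
    surface = vapply(ent, `[[`, character(1L), "surface")
  )

  normalizations <- tibble::tibble(
    norm_id = character(), entity_id = character(),
    resource = character(), referent = character()
  )
  if (!is.null(a2_path)) {
    if (!file.exists(a2_path)) stop("no such file: ", a2_path)
    nl <- readLines(a2_path, warn = FALSE, encoding = "UTF-8")
    nl <- nl[nzchar(nl)]
    rows <- lapply(seq_along(nl), function(i) {
      parts <- strsplit(nl[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !grepl("^N[0-9]+$", parts[[1L]])) {
        stop(sprintf("%s:%d: malformed normalization line: %s",
                     a2_path, i, nl[[i]]))
      }
      fields <- strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]]
      ann <- grep("^Annotation:", fields, value = TRUE)
      ref <- grep("^Referent:", fields, value = TRUE)
      if (length(ann) != 1L || length(ref) != 1L) {
        stop(sprintf("%s:%d: missing Annotation:/Referent: field", a2_path, i))
      }
      tibble::tibble(
        norm_id = parts[[1L]],
        entity_id = sub("^Annotation:", "", ann),
        resource = fields[[1L]],
        referent = sub("^Referent:", "", ref)
      )
    })
    normalizations <- do.call(rbind, rows)
    unknown <- setdiff(normalizations$entity_id, mentions$entity_id)
    if (length(unknown) > 0L) {
      stop("normalization(s) refer to unknown entity id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  list(mentions = mentions, normalizations = normalizations)
}

#' Write an .a1 entity file
#'
#' @param mentions Tibble as returned by [read_standoff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_a1 <- function(mentions, path) {
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    sp <- mentions$spans[[i]]
    frag <- paste(apply(sp, 1L, paste, collapse = " "), collapse = ";")
    sprintf("%s\t%s %s\t%s", mentions$entity_id[[i]], mentions$type[[i]],
            frag, mentions$surface[[i]])
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write predictions as an .a2 normalization file
#'
#' One `N` line per prediction with status `"ok"`, using its top-ranked
#' concept; mentions without a vector are skipped, counted, and returned as a
#' skip list (also logged to standard error), never written as lines.
#' `read_standoff()` on the output round-trips the (entity id, referent)
#' pairs.
#'
#' @param preds List of [predict_concepts()] results whose `mention` fields
#'   hold entity ids (e.g. `"T1"`).
#' @param resource_name Resource field of the `N` lines (e.g. `"OntoBiotope"`).
#' @param path Output `.a2` path.
#' @return Invisibly, a list with `n_written` and `skipped` (entity ids).
#' @export
write_predictions <- function(preds, resource_name, path) {
  ok <- vapply(preds, function(p) p$status == "ok", logical(1L))
  skipped <- vapply(preds[!ok], `[[`, character(1L), "mention")
  lines <- character(sum(ok))
  k <- 0L
  for (p in preds[ok]) {
    k <- k + 1L
    lines[[k]] <- sprintf("N%d\t%s Annotation:%s Referent:%s",
                          k, resource_name, p$mention,
                          p$ranking$concept[[1L]])
  }
  writeLines(lines, path, useBytes = TRUE)
  if (length(skipped) > 0L) {
    message("write_predictions: skipped ", length(skipped),
            " mention(s) without vector: ", paste(skipped, collapse = ", "))
  }
  invisible(list(n_written = k, skipped = skipped))
}
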