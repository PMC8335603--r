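#' Construct a question graph (meta-graph)
#'
#' A question graph is a small template whose matches in a knowledge graph
#' constitute answers. Each question node (qnode) is either pinned to a
#' CURIE, constrained to an ontology category, or both; each question edge
#' (qedge) joins two qnodes and may optionally constrain the predicate.
#' The question must be connected and free of self-loops.
#'
#' @param qnodes data.frame with columns `qid`, `curie` (NA when not
#'   pinned), `category` (NA when untyped).
#' @param qedges data.frame with columns `qeid`, `source`, `target`,
#'   `predicate` (NA when unconstrained); may have zero rows.
#' @return an object of class `question_graph`.
#' @export
question_graph <- function(qnodes, qedges = NULL) {
  qnodes <- as.data.frame(qnodes, stringsAsFactors = FALSE)
  if (is.null(qedges) || nrow(as.data.frame(qedges)) == 0L) {
    qedges <- data.frame(
      qeid = character(0), source = character(0), target = character(0),
      predicate = character(0), stringsAsFactors = FALSE
    )
  } else {
    qedges <- as.data.frame(qedges, stringsAsFactors = FALSE)
  }
  for (col in c("qid", "curie", "category")) {
    if (!col %in% names(qnodes)) stop(sprintf("qnodes are missing column '%s'", col), call. = FALSE)
  }
  for (col in c("qeid", "source", "target")) {
    if (!col %in% names(qedges)) stop(sprintf("qedges are missing column '%s'", col), call. = FALSE)
  }
  if (!"predicate" %in% names(qedges)) qedges$predicate <- rep(NA_character_, nrow(qedges))
  if (nrow(qnodes) == 0L) stop("a question needs at least one qnode", call. = FALSE)
  if (anyDuplicated(qnodes$qid)) stop("duplicate qnode labels", call. = FALSE)
  if (anyDuplicated(qedges$qeid)) stop("duplicate qedge labels", call. = FALSE)

  unconstrained <- is.na(qnodes$curie) & is.na(qnodes$category)
  if (any(unconstrained)) {
    stop(sprintf(
      "qnode '%s' has neither a pinned CURIE nor a category constraint",
      qnodes$qid[which(unconstrained)[1L]]
    ), call. = FALSE)
  }
  qnodes$curie[!is.na(qnodes$curie)] <- curie(qnodes$curie[!is.na(qnodes$curie)])

  for (side in c("source", "target")) {
    bad <- !(qedges[[side]] %in% qnodes$qid)
    if (any(bad)) {
      stop(sprintf(
        "qedge '%s' references missing qnode '%s'",
        qedges$qeid[which(bad)[1L]], qedges[[side]][which(bad)[1L]]
      ), call. = FALSE)
    }
  }
  if (any(qedges$source == qedges$target)) stop("qedge self-loops are not allowed", call. = FALSE)

  # connectivity over the undirected qedge structure
  reached <- qnodes$qid[1L]
  repeat {
    nxt <- unique(c(
      qedges$target[qedges$source %in% reached],
      qedges$source[qedges$target %in% reached]
    ))
    nxt <- setdiff(nxt, reached)
    if (length(nxt) == 0L) break
    reached <- c(reached, nxt)
  }
  if (length(reached) < nrow(qnodes)) {
    stop("question graph is disconnected", call. = FALSE)
  }

  structure(list(qnodes = qnodes, qedges = qedges), class = "question_graph")
}

#' Parse a question graph from a YAML/JSON document
#'
#' The document has a `nodes` list of `{qid, curie?, category?}` entries and
#' an optional `edges` list of `{qeid, source, target, predicate?}` entries.
#'
#' @param doc path to a YAML (or JSON, a YAML subset) file, or a single
#'   string holding the document text.
#' @return a validated [question_graph()].
#' @export
parse_question <- function(doc) {
  parsed <- if (length(doc) == 1L && file.exists(doc)) {
    yaml::read_yaml(doc)
  } else {
    yaml::yaml.load(paste(doc, collapse = "\n"))
  }
  if (is.null(parsed$nodes)) stop("question document has no 'nodes' entry", call. = FALSE)
  qnodes <- do.call(rbind, lapply(parsed$nodes, function(n) {
    if (is.null(n$qid)) stop("question node is missing 'qid'", call. = FALSE)
    data.frame(
      qid = as.character(n$qid),
      curie = as.character(n$curie %||% NA_character_),
      category = as.character(n$category %||% NA_character_),
      stringsAsFactors = FALSE
    )
  }))
  qedges <- NULL
  if (!is.null(parsed$edges) && length(parsed$edges) > 0L) {
    qedges <- do.call(rbind, lapply(parsed$edges, function(e) {
      for (f in c("qeid", "source", "target")) {
        if (is.null(e[[f]])) stop(sprintf("question edge is missing '%s'", f), call. = FALSE)
      }
      data.frame(
        qeid = as.character(e$qeid), source = as.character(e$source),
        target = as.character(e$target),
        predicate = as.character(e$predicate %||% NA_character_),
        stringsAsFactors = FALSE
      )
    }))
  }
  question_graph(qnodes, qedges)
}

#' Serialize a question graph to YAML text
#'
#' @param qg a [question_graph()].
#' @param path optional output path; when `NULL` the YAML text is returned.
#' @return the YAML text (invisibly when written to `path`).
#' @export
write_question <- function(qg, path = NULL) {
  stopifnot(inherits(qg, "question_graph"))
  nodes <- lapply(seq_len(nrow(qg$qnodes)), function(i) {
    n <- list(qid = qg$qnodes$qid[i])
    if (!is.na(qg$qnodes$curie[i])) n$curie <- qg$qnodes$curie[i]
    if (!is.na(qg$qnodes$category[i])) n$category <- qg$qnodes$category[i]
    n
  })
  edges <- lapply(seq_len(nrow(qg$qedges)), function(i) {
    e <- list(
      qeid = qg$qedges$qeid[i], source = qg$qedges$source[i],
      target = qg$qedges$target[i]
    )
    if (!is.na(qg$qedges$predicate[i])) e$predicate <- qg$qedges$predicate[i]
    e
  })
  txt <- yaml::as.yaml(list(nodes = nodes, edges = edges))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @export
print.question_graph <- function(x, ...) {
  cat(sprintf(
    "<question_graph> %d qnodes, %d qedges\n", nrow(x$qnodes), nrow(x$qedges)
  ))
  invisible(x)
}
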