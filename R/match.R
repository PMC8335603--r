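#' Match a question graph against a knowledge graph
#'
#' Finds the complete set of answer subgraphs: every injective assignment of
#' graph nodes to qnodes such that pinned qnodes map to their CURIE, typed
#' qnodes map to nodes carrying a subtype of the constraint, and every qedge
#' is witnessed by at least one graph edge between the bound endpoints
#' (direction ignored; an exact predicate match is required when the qedge
#' constrains the predicate). Parallel witnessing edges are collected into a
#' single answer's edge bindings — multiple sources strengthen an answer,
#' they do not multiply it.
#'
#' The search backtracks over qnodes ordered most-constrained-first
#' (smallest candidate set), which is ample at desk scale. A pinned CURIE
#' absent from the graph yields zero answers, not an error. Output order is
#' deterministic: answers sort lexicographically on their bindings taken in
#' sorted-qid order.
#'
#' @param kg a [knowledge_graph()].
#' @param qg a [question_graph()] over the same ontology.
#' @return a list of `answer_subgraph` objects, each with `node_bindings`
#'   (named character, qid to CURIE) and `edge_bindings` (named list, qeid to
#'   integer edge ids into `kg$edges$eid`).
#' @export
match_question <- function(kg, qg) {
  stopifnot(inherits(kg, "knowledge_graph"), inherits(qg, "question_graph"))
  ont <- kg$ontology

  node_matches_category <- function(cats, constraint) {
    any(vapply(cats, function(cc) is_subtype(ont, cc, constraint), logical(1)))
  }

  candidates <- lapply(seq_len(nrow(qg$qnodes)), function(i) {
    pin <- qg$qnodes$curie[i]
    cat <- qg$qnodes$category[i]
    ids <- kg$nodes$id
    if (!is.na(pin)) ids <- ids[ids == pin]
    if (!is.na(cat) && length(ids) > 0L) {
      if (!cat %in% ont$categories) stop(sprintf("unknown category '%s'", cat), call. = FALSE)
      keep <- vapply(match(ids, kg$nodes$id), function(j) {
        node_matches_category(kg$nodes$categories[[j]], cat)
      }, logical(1))
      ids <- ids[keep]
    }
    sort(ids)
  })
  names(candidates) <- qg$qnodes$qid

  # undirected endpoint-pair -> edge row lookup
  edge_lookup <- list()
  if (nrow(kg$edges) > 0L) {
    keys <- pair_key(kg$edges$subject, kg$edges$object)
    edge_lookup <- split(seq_len(nrow(kg$edges)), keys)
  }

  witness_rows <- function(a, b, predicate) {
    rows <- edge_lookup[[pair_key(a, b)]]
    if (is.null(rows)) return(integer(0))
    if (!is.na(predicate)) rows <- rows[kg$edges$predicate[rows] == predicate]
    rows
  }

  order_q <- order(vapply(candidates, length, integer(1)))
  qids_in_order <- qg$qnodes$qid[order_q]

  qe_src <- qg$qedges$source
  qe_tgt <- qg$qedges$target

  answers <- list()
  assign_next <- function(k, bound) {
    if (k > length(qids_in_order)) {
      nb <- unlist(bound[sort(names(bound))]) # named character, qid -> CURIE
      eb <- lapply(seq_len(nrow(qg$qedges)), function(j) {
        sort(kg$edges$eid[witness_rows(bound[[qe_src[j]]], bound[[qe_tgt[j]]], qg$qedges$predicate[j])])
      })
      names(eb) <- qg$qedges$qeid
      answers[[length(answers) + 1L]] <<- structure(
        list(node_bindings = nb, edge_bindings = eb),
        class = "answer_subgraph"
      )
      return(invisible(NULL))
    }
    qid <- qids_in_order[k]
    for (cand in candidates[[qid]]) {
      if (cand %in% unlist(bound, use.names = FALSE)) next # injectivity
      trial <- bound
      trial[[qid]] <- cand
      ok <- TRUE
      for (j in seq_len(nrow(qg$qedges))) {
        s <- trial[[qe_src[j]]]
        t <- trial[[qe_tgt[j]]]
        if (is.null(s) || is.null(t)) next
        if (length(witness_rows(s, t, qg$qedges$predicate[j])) == 0L) {
          ok <- FALSE
          break
        }
      }
      if (ok) assign_next(k + 1L, trial)
    }
    invisible(NULL)
  }
  assign_next(1L, stats::setNames(list(), character(0)))

  if (length(answers) > 1L) {
    key <- vapply(answers, function(a) paste(a$node_bindings, collapse = "\r"), character(1))
    answers <- answers[order(key)]
  }
  answers
}

#' @export
print.answer_subgraph <- function(x, ...) {
  cat("<answer_subgraph>\n")
  for (qid in names(x$node_bindings)) {
    cat(sprintf("  %s -> %s\n", qid, x$node_bindings[[qid]]))
  }
  invisible(x)
}

#' Write an answer list as structured JSON text
#'
#' One record per answer, in the deterministic order returned by
#' [match_question()], listing node bindings and edge bindings (by stable
#' edge id).
#'
#' @param answers list of answer subgraphs.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_answers <- function(answers, path) {
  recs <- lapply(answers, function(a) {
    list(
      node_bindings = as.list(a$node_bindings),
      edge_bindings = a$edge_bindings
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
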