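#' Construct a typed property knowledge graph
#'
#' Nodes are CURIE-identified entities carrying one or more ontology
#' categories (most specific first); edges are directed provenance-bearing
#' assertions (subject, predicate, object, primary source, curated
#' publication list). Degree and question matching treat edges as
#' undirected: an answer path is traversed without regard to assertion
#' direction. Parallel edges with the same endpoints but different
#' predicate or source are kept distinct.
#'
#' @param nodes data.frame with columns `id` (CURIE), `name`, and
#'   `categories` (list-column of character vectors, or a character column of
#'   pipe-separated tokens).
#' @param edges data.frame with columns `subject`, `predicate`, `object`,
#'   `primary_source`, and `publications` (list-column of PMID strings, or a
#'   character column of pipe-separated PMIDs).
#' @param ontology a [type_ontology()]; defaults to [default_ontology()].
#' @return an object of class `knowledge_graph` with elements `nodes`,
#'   `edges` (with a stable integer `eid` column), and `ontology`.
#' @export
knowledge_graph <- function(nodes, edges, ontology = default_ontology()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges), inherits(ontology, "type_ontology"))

  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)

  for (col in c("id", "name", "categories")) {
    if (!col %in% names(nodes)) stop(sprintf("nodes are missing column '%s'", col), call. = FALSE)
  }
  for (col in c("subject", "predicate", "object", "primary_source", "publications")) {
    if (!col %in% names(edges)) stop(sprintf("edges are missing column '%s'", col), call. = FALSE)
  }

  nodes$id <- curie(nodes$id)
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    stop(sprintf("duplicate node id(s): %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (!is.list(nodes$categories)) nodes$categories <- lapply(nodes$categories, split_pipe)
  for (i in seq_len(nrow(nodes))) {
    cats <- nodes$categories[[i]]
    if (length(cats) == 0L) {
      stop(sprintf("node '%s' has no category", nodes$id[i]), call. = FALSE)
    }
    unknown <- setdiff(cats, ontology$categories)
    if (length(unknown) > 0L) {
      stop(sprintf(
        "node '%s' has unknown category '%s'", nodes$id[i], unknown[1L]
      ), call. = FALSE)
    }
  }

  if (nrow(edges) > 0L) {
    edges$subject <- curie(edges$subject)
    edges$object <- curie(edges$object)
    if (!is.list(edges$publications)) edges$publications <- lapply(edges$publications, split_pipe)
    edges$publications <- lapply(edges$publications, function(p) unique(as.character(p)))
    self <- edges$subject == edges$object
    if (any(self)) {
      stop(sprintf(
        "edge row %d is a self-loop on '%s'", which(self)[1L], edges$subject[which(self)[1L]]
      ), call. = FALSE)
    }
    for (side in c("subject", "object")) {
      missing <- !(edges[[side]] %in% nodes$id)
      if (any(missing)) {
        row <- which(missing)[1L]
        stop(sprintf(
          "edge row %d references absent node id '%s'", row, edges[[side]][row]
        ), call. = FALSE)
      }
    }
  } else {
    edges <- data.frame(
      subject = character(0), predicate = character(0), object = character(0),
      primary_source = character(0), stringsAsFactors = FALSE
    )
    edges$publications <- list()
  }
  edges$eid <- seq_len(nrow(edges))

  structure(
    list(nodes = nodes, edges = edges, ontology = ontology),
    class = "knowledge_graph"
  )
}

#' Load a knowledge graph from KGX-style TSV tables
#'
#' The nodes table has header `id	name	category` with `category`
#' holding pipe-separated ontology tokens, most specific first. The edges
#' table has header `subject	predicate	object	primary_source	publications`
#' with `publications` holding pipe-separated PMIDs (empty allowed).
#' Malformed rows are rejected with an error naming the offending row or
#' identifier; nothing is skipped silently.
#'
#' @param nodes_path,edges_path paths to the TSV files.
#' @param ontology a [type_ontology()].
#' @return a [knowledge_graph()].
#' @export
load_graph <- function(nodes_path, edges_path, ontology = default_ontology()) {
  nt <- read_tsv_raw(nodes_path, c("id", "name", "category"))
  et <- read_tsv_raw(edges_path, c("subject", "predicate", "object", "primary_source", "publications"))
  nodes <- data.frame(id = nt$id, name = nt$name, stringsAsFactors = FALSE)
  nodes$categories <- lapply(nt$category, split_pipe)
  edges <- data.frame(
    subject = et$subject, predicate = et$predicate, object = et$object,
    primary_source = et$primary_source, stringsAsFactors = FALSE
  )
  edges$publications <- lapply(et$publications, split_pipe)
  knowledge_graph(nodes, edges, ontology)
}

#' Write a knowledge graph to KGX-style TSV tables
#'
#' Rows are written in canonical order (nodes by CURIE; edges by subject,
#' predicate, object, source), so `write_graph(load_graph(x))` is
#' byte-identical for canonically sorted input.
#'
#' @param kg a [knowledge_graph()].
#' @param nodes_path,edges_path output paths.
#' @return invisibly, the two paths.
#' @export
write_graph <- function(kg, nodes_path, edges_path) {
  stopifnot(inherits(kg, "knowledge_graph"))
  nt <- data.frame(
    id = kg$nodes$id, name = kg$nodes$name,
    category = vapply(kg$nodes$categories, join_pipe, character(1)),
    stringsAsFactors = FALSE
  )
  nt <- nt[order(nt$id), , drop = FALSE]
  et <- data.frame(
    subject = kg$edges$subject, predicate = kg$edges$predicate,
    object = kg$edges$object, primary_source = kg$edges$primary_source,
    publications = vapply(kg$edges$publications, join_pipe, character(1)),
    stringsAsFactors = FALSE
  )
  et <- et[order(et$subject, et$predicate, et$object, et$primary_source, et$publications), , drop = FALSE]
  write_tsv_raw(nt, nodes_path)
  write_tsv_raw(et, edges_path)
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Node degree, direction ignored
#'
#' Counts incident edges of a node; parallel edges each count once.
#'
#' @param kg a [knowledge_graph()].
#' @param node a CURIE present in the graph.
#' @return non-negative integer.
#' @export
node_degree <- function(kg, node) {
  stopifnot(inherits(kg, "knowledge_graph"))
  node <- curie(node)
  if (!node %in% kg$nodes$id) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  sum(kg$edges$subject == node) + sum(kg$edges$object == node)
}

# degrees for all nodes, as a named integer vector (direction ignored)
all_degrees <- function(kg) {
  deg <- stats::setNames(integer(nrow(kg$nodes)), kg$nodes$id)
  if (nrow(kg$edges) > 0L) {
    tab <- table(c(kg$edges$subject, kg$edges$object))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

cypher_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

cypher_str_list <- function(xs) {
  paste0("[", paste0('"', cypher_escape(xs), '"', collapse = ", "), "]")
}

#' Export a knowledge graph as Cypher CREATE statements
#'
#' Produces deterministic UTF-8 text, one statement per line, suitable for
#' execution against a Cypher-speaking property-graph store: nodes first
#' (sorted by CURIE, labelled with their most specific category), then edges
#' (sorted by subject, predicate, object) created by matching endpoints on
#' their `id` property. Export-only; there is no Cypher import path.
#'
#' @param kg a [knowledge_graph()].
#' @return a single character string (empty for an empty graph).
#' @export
export_cypher <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  nodes <- kg$nodes[order(kg$nodes$id), , drop = FALSE]
  node_lines <- vapply(seq_len(nrow(nodes)), function(i) {
    cats <- nodes$categories[[i]]
    sprintf(
      'CREATE (:%s {id: "%s", name: "%s", categories: %s});',
      cats[1L], cypher_escape(nodes$id[i]), cypher_escape(nodes$name[i]),
      cypher_str_list(cats)
    )
  }, character(1))
  edges <- kg$edges[order(kg$edges$subject, kg$edges$predicate, kg$edges$object, kg$edges$eid), , drop = FALSE]
  edge_lines <- vapply(seq_len(nrow(edges)), function(i) {
    pubs <- edges$publications[[i]]
    pub_lit <- if (length(pubs) == 0L) "[]" else cypher_str_list(pubs)
    sprintf(
      'MATCH (a {id: "%s"}), (b {id: "%s"}) CREATE (a)-[:%s {primary_source: "%s", publications: %s}]->(b);',
      cypher_escape(edges$subject[i]), cypher_escape(edges$object[i]),
      edges$predicate[i], cypher_escape(edges$primary_source[i]), pub_lit
    )
  }, character(1))
  lines <- c(node_lines, edge_lines)
  if (length(lines) == 0L) "" else paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}
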