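# Independent oracles used across the suite. These deliberately share no
# code with the package's own search / linear-algebra paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force answer enumeration: loops over every injective assignment of
# graph nodes to qnodes and checks each constraint directly against the
# edge list. Returns a sorted character vector of canonical binding strings.
oracle_match_bindings <- function(kg, qg) {
  nq <- nrow(qg$qnodes)
  cand <- lapply(seq_len(nq), function(i) {
    ids <- kg$nodes$id
    keep <- vapply(seq_along(ids), function(j) {
      ok <- TRUE
      if (!is.na(qg$qnodes$curie[i])) ok <- ids[j] == qg$qnodes$curie[i]
      if (ok && !is.na(qg$qnodes$category[i])) {
        ok <- any(vapply(
          kg$nodes$categories[[j]],
          function(cc) is_subtype(kg$ontology, cc, qg$qnodes$category[i]),
          logical(1)
        ))
      }
      ok
    }, logical(1))
    ids[keep]
  })
  names(cand) <- qg$qnodes$qid
  if (any(lengths(cand) == 0L)) return(character(0))
  grid <- expand.grid(cand, stringsAsFactors = FALSE)

  has_witness <- function(s, t, predicate) {
    hit <- (kg$edges$subject == s & kg$edges$object == t) |
      (kg$edges$subject == t & kg$edges$object == s)
    if (!is.na(predicate)) hit <- hit & kg$edges$predicate == predicate
    any(hit)
  }

  out <- character(0)
  for (r in seq_len(nrow(grid))) {
    row <- unlist(grid[r, , drop = FALSE])
    if (anyDuplicated(row)) next
    ok <- TRUE
    for (j in seq_len(nrow(qg$qedges))) {
      if (!has_witness(row[[qg$qedges$source[j]]], row[[qg$qedges$target[j]]], qg$qedges$predicate[j])) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      qids <- sort(qg$qnodes$qid)
      out <- c(out, paste(paste0(qids, "=", row[qids]), collapse = ";"))
    }
  }
  sort(out)
}

answer_binding_strings <- function(answers) {
  sort(vapply(answers, function(a) {
    qids <- sort(names(a$node_bindings))
    paste(paste0(qids, "=", a$node_bindings[qids]), collapse = ";")
  }, character(1)))
}

# Effective resistance by direct linear solve: ground terminal t, inject a
# unit current at s, and read off the potential at s. Independent of the
# package's pseudoinverse route.
oracle_resistance <- function(nodes, from, to, resistance, s, t) {
  m <- length(nodes)
  idx <- stats::setNames(seq_len(m), nodes)
  L <- matrix(0, m, m)
  for (b in seq_along(from)) {
    i <- idx[[from[b]]]
    j <- idx[[to[b]]]
    g <- 1 / resistance[b]
    L[i, i] <- L[i, i] + g
    L[j, j] <- L[j, j] + g
    L[i, j] <- L[i, j] - g
    L[j, i] <- L[j, i] - g
  }
  keep <- setdiff(seq_len(m), idx[[t]])
  rhs <- numeric(m)
  rhs[idx[[s]]] <- 1
  v <- solve(L[keep, keep, drop = FALSE], rhs[keep])
  v[match(idx[[s]], keep)]
}

# Random connected circuit on <= max_nodes nodes: a spanning tree plus a few
# extra branches, with log-uniform branch resistances.
random_circuit <- function(seed, max_nodes = 6L) {
  set.seed(seed)
  m <- sample(2:max_nodes, 1L)
  nodes <- paste0("v", seq_len(m))
  from <- character(0)
  to <- character(0)
  if (m > 1L) {
    for (i in 2:m) {
      from <- c(from, nodes[sample.int(i - 1L, 1L)])
      to <- c(to, nodes[i])
    }
  }
  extra <- sample(0:3, 1L)
  for (k in seq_len(extra)) {
    pair <- sample(m, 2L)
    from <- c(from, nodes[pair[1L]])
    to <- c(to, nodes[pair[2L]])
  }
  list(
    nodes = nodes, from = from, to = to,
    resistance = exp(stats::runif(length(from), log(0.1), log(10))),
    s = nodes[1L], t = nodes[m]
  )
}

# Random connected question graph over 2-4 qnodes against a given KG:
# a random tree template with a mix of pinned, typed, and predicate
# constraints drawn from the graph itself (plus occasional absent pins).
random_question <- function(kg, seed) {
  set.seed(seed)
  nq <- sample(2:4, 1L)
  qids <- paste0("q", seq_len(nq))
  leaves <- setdiff(kg$ontology$categories, kg$ontology$root)
  curie_pool <- c(kg$nodes$id, "FIX:ABSENT")
  curies <- rep(NA_character_, nq)
  cats <- rep(NA_character_, nq)
  for (i in seq_len(nq)) {
    mode <- sample(c("pin", "cat", "both"), 1L, prob = c(0.3, 0.55, 0.15))
    if (mode %in% c("pin", "both")) curies[i] <- sample(curie_pool, 1L)
    if (mode %in% c("cat", "both")) {
      cats[i] <- sample(c(leaves, kg$ontology$root), 1L)
    }
  }
  pred_pool <- unique(kg$edges$predicate)
  src <- character(0)
  tgt <- character(0)
  pred <- character(0)
  for (i in 2:nq) {
    src <- c(src, qids[sample.int(i - 1L, 1L)])
    tgt <- c(tgt, qids[i])
    pred <- c(pred, if (length(pred_pool) > 0L && stats::runif(1) < 0.3) {
      sample(pred_pool, 1L)
    } else {
      NA_character_
    })
  }
  question_graph(
    qnodes = data.frame(qid = qids, curie = curies, category = cats, stringsAsFactors = FALSE),
    qedges = data.frame(
      qeid = paste0("qe", seq_along(src)), source = src, target = tgt,
      predicate = pred, stringsAsFactors = FALSE
    )
  )
}

# Minimal parser for the package's own Cypher export, enough for the
# round-trip isomorphism check (handles the quote/backslash escapes the
# exporter emits).
cypher_unescape <- function(x) {
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

parse_cypher_export <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines)]
  node_re <- '^CREATE \\(:[^ ]+ \\{id: "(.*)", name: "(.*)", categories: \\[(.*)\\]\\}\\);$'
  edge_re <- '^MATCH \\(a \\{id: "(.*)"\\}\\), \\(b \\{id: "(.*)"\\}\\) CREATE \\(a\\)-\\[:([^ ]+) \\{primary_source: "(.*)", publications: \\[(.*)\\]\\}\\]->\\(b\\);$'
  parse_str_list <- function(s) {
    if (!nzchar(s)) return(character(0))
    parts <- strsplit(s, '", "', fixed = TRUE)[[1L]]
    cypher_unescape(gsub('^"|"$', "", parts))
  }
  nodes <- list()
  edges <- list()
  for (ln in lines) {
    if (grepl(node_re, ln)) {
      m <- regmatches(ln, regexec(node_re, ln))[[1L]]
      nodes[[length(nodes) + 1L]] <- list(
        id = cypher_unescape(m[2L]), name = cypher_unescape(m[3L]),
        categories = parse_str_list(m[4L])
      )
    } else if (grepl(edge_re, ln)) {
      m <- regmatches(ln, regexec(edge_re, ln))[[1L]]
      edges[[length(edges) + 1L]] <- list(
        subject = cypher_unescape(m[2L]), object = cypher_unescape(m[3L]),
        predicate = m[4L], primary_source = cypher_unescape(m[5L]),
        publications = parse_str_list(m[6L])
      )
    } else {
      stop(sprintf("unparseable Cypher line: %s", ln))
    }
  }
  list(nodes = nodes, edges = edges)
}

# canonical comparable form of a knowledge graph
kg_canonical <- function(kg) {
  nodes <- vapply(order(kg$nodes$id), function(i) {
    paste(kg$nodes$id[i], kg$nodes$name[i], paste(kg$nodes$categories[[i]], collapse = "|"), sep = "\t")
  }, character(1))
  edges <- sort(vapply(seq_len(nrow(kg$edges)), function(i) {
    paste(kg$edges$subject[i], kg$edges$predicate[i], kg$edges$object[i],
      kg$edges$primary_source[i], paste(sort(kg$edges$publications[[i]]), collapse = "|"),
      sep = "\t"
    )
  }, character(1)))
  list(nodes = nodes, edges = edges)
}

parsed_cypher_canonical <- function(parsed) {
  nodes <- sort(vapply(parsed$nodes, function(n) {
    paste(n$id, n$name, paste(n$categories, collapse = "|"), sep = "\t")
  }, character(1)))
  edges <- sort(vapply(parsed$edges, function(e) {
    paste(e$subject, e$predicate, e$object, e$primary_source,
      paste(sort(e$publications), collapse = "|"),
      sep = "\t"
    )
  }, character(1)))
  list(nodes = nodes, edges = edges)
}

# empty knowledge graph helper
empty_kg <- function() {
  nodes <- data.frame(id = character(0), name = character(0), stringsAsFactors = FALSE)
  nodes$categories <- list()
  edges <- data.frame(
    subject = character(0), predicate = character(0), object = character(0),
    primary_source = character(0), stringsAsFactors = FALSE
  )
  edges$publications <- list()
  knowledge_graph(nodes, edges)
}

# tiny graph builder for hand-constructed cases
mini_kg <- function(node_spec, edge_spec) {
  nodes <- data.frame(
    id = names(node_spec), name = names(node_spec), stringsAsFactors = FALSE
  )
  nodes$categories <- lapply(unname(node_spec), identity)
  edges <- do.call(rbind, lapply(edge_spec, function(e) {
    data.frame(
      subject = e[[1L]], predicate = e[[2L]], object = e[[3L]],
      primary_source = if (length(e) >= 4L) e[[4L]] else "CTD",
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(edges)) {
    edges <- data.frame(
      subject = character(0), predicate = character(0), object = character(0),
      primary_source = character(0), stringsAsFactors = FALSE
    )
    edges$publications <- list()
  } else {
    edges$publications <- lapply(edge_spec, function(e) if (length(e) >= 5L) e[[5L]] else character(0))
  }
  knowledge_graph(nodes, edges)
}
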