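#' Ranking parameters
#'
#' Constants of the answer-scoring model. Publication support on an edge is
#' `S = curated_pub_weight * n_curated + omnicorp_pub_weight * n_cooccurrence`;
#' curated counts come from the knowledge sources' own publication lists and
#' are weighted above raw literature co-occurrence
#' (`omnicorp_pub_weight <= curated_pub_weight`). Support maps to an edge
#' weight in (0,1) through the saturating form
#' `w = (S + eps) / (S + eps + k)`, so edge resistance `1/w` is always
#' finite and positive; `saturation_k` sets how many (weighted)
#' publications give weight 1/2, and `support_floor_eps` keeps unsupported
#' edges conductive. The final score blends confidence and informativeness
#' as a weighted geometric mean with exponent `combine_gamma` on confidence.
#'
#' @param curated_pub_weight positive; weight of one curated publication
#'   (default 1.0).
#' @param omnicorp_pub_weight in (0, curated_pub_weight]; weight of one
#'   co-occurrence publication (default 0.25).
#' @param saturation_k positive; half-saturation constant of the weight map
#'   (default 10).
#' @param support_floor_eps positive; support floor for unsupported edges and
#'   informativeness floor in the combined score (default 0.01).
#' @param combine_gamma in \[0,1\]; geometric-mean exponent on confidence
#'   (default 0.8, confidence-dominant).
#' @return an object of class `ranking_params`.
#' @export
ranking_params <- function(curated_pub_weight = 1.0,
                           omnicorp_pub_weight = 0.25,
                           saturation_k = 10.0,
                           support_floor_eps = 0.01,
                           combine_gamma = 0.8) {
  stopifnot(
    curated_pub_weight > 0,
    omnicorp_pub_weight > 0, omnicorp_pub_weight <= curated_pub_weight,
    saturation_k > 0, support_floor_eps > 0,
    combine_gamma >= 0, combine_gamma <= 1
  )
  structure(
    list(
      curated_pub_weight = curated_pub_weight,
      omnicorp_pub_weight = omnicorp_pub_weight,
      saturation_k = saturation_k,
      support_floor_eps = support_floor_eps,
      combine_gamma = combine_gamma
    ),
    class = "ranking_params"
  )
}

#' Load ranking parameters from a YAML config file
#'
#' Flat keys matching the [ranking_params()] arguments override defaults;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `ranking_params` object.
#' @export
read_ranking_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(ranking_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown ranking parameter(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(ranking_params, cfg)
}

#' Publication support, weight, and resistance of one bound qedge
#'
#' The curated count is the size of the union of curated publication lists
#' across the parallel witness edges; the co-occurrence count is the number
#' of abstracts mentioning both endpoints. Support, weight, and resistance
#' follow the [ranking_params()] model.
#'
#' @param edges data.frame of witness edge rows (a subset of `kg$edges`)
#'   bound to one qedge; all rows share the same endpoint pair.
#' @param index a `cooc_index` (or `NULL` for no co-occurrence support).
#' @param params a [ranking_params()].
#' @return a list of class `edge_support` with fields `curated_count`,
#'   `omnicorp_count`, `support`, `weight`, `resistance`.
#' @export
edge_support <- function(edges, index, params = ranking_params()) {
  stopifnot(is.data.frame(edges), nrow(edges) >= 1L, inherits(params, "ranking_params"))
  curated <- length(unique(unlist(edges$publications)))
  omnicorp <- if (is.null(index)) 0L else {
    cooccurrence_count(index, edges$subject[1L], edges$object[1L])
  }
  support <- params$curated_pub_weight * curated + params$omnicorp_pub_weight * omnicorp
  weight <- (support + params$support_floor_eps) /
    (support + params$support_floor_eps + params$saturation_k)
  structure(
    list(
      curated_count = curated, omnicorp_count = omnicorp,
      support = support, weight = weight, resistance = 1 / weight
    ),
    class = "edge_support"
  )
}

#' Two-terminal effective resistance of a resistor network
#'
#' Computed from the Moore-Penrose pseudoinverse of the weighted graph
#' Laplacian (branch conductance = 1/resistance):
#' `R_eff(s, t) = (e_s - e_t)' L^+ (e_s - e_t)`. Parallel branches between
#' the same node pair add conductances. For a simple series path this is
#' the plain sum of branch resistances.
#'
#' @param nodes character vector of node labels.
#' @param from,to character vectors of branch endpoints.
#' @param resistance positive numeric vector of branch resistances.
#' @param s,t terminal labels.
#' @return positive real.
#' @export
effective_resistance <- function(nodes, from, to, resistance, s, t) {
  stopifnot(
    length(from) == length(to), length(from) == length(resistance),
    all(resistance > 0), s %in% nodes, t %in% nodes
  )
  if (s == t) return(0)
  m <- length(nodes)
  idx <- stats::setNames(seq_len(m), nodes)
  # connectivity between s and t over the branch structure
  reached <- s
  repeat {
    nxt <- unique(c(to[from %in% reached], from[to %in% reached]))
    nxt <- setdiff(nxt, reached)
    if (length(nxt) == 0L) break
    reached <- c(reached, nxt)
  }
  if (!t %in% reached) stop("terminals are not connected", call. = FALSE)

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
  Lp <- MASS::ginv(L)
  e <- numeric(m)
  e[idx[[s]]] <- 1
  e[idx[[t]]] <- -1
  drop(t(e) %*% Lp %*% e)
}

# terminal qid pairs for answer_resistance given the question's pinned qnodes
terminal_pairs <- function(qg) {
  pinned <- qg$qnodes$qid[!is.na(qg$qnodes$curie)]
  pool <- if (length(pinned) >= 2L) pinned else qg$qnodes$qid
  if (length(pool) < 2L) {
    return(matrix(character(0), ncol = 2))
  }
  pairs <- utils::combn(sort(pool), 2L)
  if (length(pinned) == 2L) {
    pairs <- pairs[, 1L, drop = FALSE] # exactly the pinned pair
  }
  t(pairs)
}

#' Effective resistance of an answer subgraph
#'
#' Builds the answer's bound-node circuit — one branch per qedge, branch
#' resistance from its [edge_support()] — and returns the two-terminal
#' effective resistance between the question's two pinned qnodes. When the
#' question does not pin exactly two qnodes, the mean pairwise effective
#' resistance over all pinned qnode pairs (or over all qnode pairs when
#' fewer than two are pinned) is used. An answer to a single-qnode question
#' has no circuit; its resistance is defined as 1 (unit resistance).
#'
#' @param answer an answer subgraph from [match_question()].
#' @param qg the matched [question_graph()].
#' @param supports named list, qeid to [edge_support()].
#' @return positive real.
#' @export
answer_resistance <- function(answer, qg, supports) {
  stopifnot(inherits(answer, "answer_subgraph"), inherits(qg, "question_graph"))
  if (nrow(qg$qedges) == 0L) return(1)
  missing <- setdiff(qg$qedges$qeid, names(supports))
  if (length(missing) > 0L) {
    stop(sprintf("missing edge support for qedge '%s'", missing[1L]), call. = FALSE)
  }
  res <- vapply(qg$qedges$qeid, function(qe) supports[[qe]]$resistance, numeric(1))
  pairs <- terminal_pairs(qg)
  vals <- vapply(seq_len(nrow(pairs)), function(r) {
    effective_resistance(
      nodes = qg$qnodes$qid,
      from = qg$qedges$source, to = qg$qedges$target, resistance = res,
      s = pairs[r, 1L], t = pairs[r, 2L]
    )
  }, numeric(1))
  mean(vals)
}

#' Map resistance to a confidence score
#'
#' `confidence = 1 / (1 + R)`: strictly decreasing in resistance, mapping
#' (0, Inf) onto (0, 1), with unit resistance at confidence 1/2.
#'
#' @param resistance positive real (vectorized).
#' @return real in (0,1).
#' @export
confidence_score <- function(resistance) {
  if (any(!is.finite(resistance)) || any(resistance <= 0)) {
    stop("resistance must be positive and finite", call. = FALSE)
  }
  1 / (1 + resistance)
}

#' Informativeness of an answer subgraph
#'
#' A specificity score rewarding answers that route through low-degree
#' (specific) nodes rather than generic hubs: the mean over bound qedges of
#' `1 - (log d(s) + log d(o)) / (2 log Dmax)`, where `d` is the endpoint's
#' degree in the full knowledge graph and `Dmax` is the graph's maximum
#' degree (clamped to at least 2). All endpoints at degree 1 give 1; all at
#' the maximum degree give 0. An answer with no qedges scores 0.
#'
#' @param answer an answer subgraph from [match_question()].
#' @param qg the matched [question_graph()].
#' @param kg the [knowledge_graph()] the answer was matched in.
#' @return real in \[0,1\].
#' @export
informativeness_score <- function(answer, qg, kg) {
  stopifnot(inherits(answer, "answer_subgraph"), inherits(kg, "knowledge_graph"))
  if (nrow(qg$qedges) == 0L) return(0)
  deg <- all_degrees(kg)
  absent <- setdiff(unname(answer$node_bindings), names(deg))
  if (length(absent) > 0L) {
    stop(sprintf("bound node '%s' is absent from the knowledge graph", absent[1L]), call. = FALSE)
  }
  dmax <- max(2L, max(deg))
  spec <- vapply(seq_len(nrow(qg$qedges)), function(j) {
    ds <- deg[[answer$node_bindings[[qg$qedges$source[j]]]]]
    do <- deg[[answer$node_bindings[[qg$qedges$target[j]]]]]
    if (ds < 1L || do < 1L) stop("bound nodes must have degree >= 1", call. = FALSE)
    1 - (log(ds) + log(do)) / (2 * log(dmax))
  }, numeric(1))
  mean(spec)
}

#' Score and rank answer subgraphs
#'
#' For each answer: per-qedge publication supports ([edge_support()]),
#' effective resistance ([answer_resistance()]), confidence
#' ([confidence_score()]), informativeness ([informativeness_score()]), and
#' the combined score `confidence^gamma * informativeness^(1-gamma)` (with
#' the informativeness floor `support_floor_eps` substituted when
#' informativeness is 0). Answers are returned sorted by score descending,
#' ties broken lexicographically on the sorted bound CURIEs, so the ranking
#' is deterministic and invariant under permutation of the input list.
#'
#' @param answers list of answer subgraphs from [match_question()].
#' @param qg the [question_graph()].
#' @param kg the [knowledge_graph()].
#' @param index a `cooc_index` (or `NULL`).
#' @param params a [ranking_params()].
#' @return an object of class `ranked_answers`: a list with a summary
#'   data.frame `table` (rank, bindings, resistance, confidence,
#'   informativeness, score), the reordered `answers`, and per-answer
#'   `supports` (named list qeid -> `edge_support`).
#' @export
rank_answers <- function(answers, qg, kg, index = NULL, params = ranking_params()) {
  stopifnot(inherits(qg, "question_graph"), inherits(kg, "knowledge_graph"))
  n <- length(answers)
  if (n == 0L) {
    return(structure(
      list(
        table = data.frame(
          rank = integer(0), bindings = character(0), resistance = numeric(0),
          confidence = numeric(0), informativeness = numeric(0), score = numeric(0)
        ),
        answers = list(), supports = list(), params = params
      ),
      class = "ranked_answers"
    ))
  }
  supports <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- answers[[i]]
    sup <- lapply(stats::setNames(qg$qedges$qeid, qg$qedges$qeid), function(qe) {
      eids <- a$edge_bindings[[qe]]
      edge_support(kg$edges[match(eids, kg$edges$eid), , drop = FALSE], index, params)
    })
    supports[[i]] <- sup
    R <- answer_resistance(a, qg, sup)
    conf <- confidence_score(R)
    info <- informativeness_score(a, qg, kg)
    info_eff <- if (info > 0) info else params$support_floor_eps
    score <- conf^params$combine_gamma * info_eff^(1 - params$combine_gamma)
    rows[[i]] <- data.frame(
      bindings = paste(sort(unname(a$node_bindings)), collapse = "|"),
      resistance = R, confidence = conf, informativeness = info, score = score,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$score, tab$bindings)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(n), tab)
  rownames(tab) <- NULL
  structure(
    list(table = tab, answers = answers[ord], supports = supports[ord], params = params),
    class = "ranked_answers"
  )
}

#' Write a ranked-answer report
#'
#' Structured JSON with, per answer: rank, node bindings, per-qedge curated
#' and co-occurrence publication counts with weight and resistance, and the
#' resistance/confidence/informativeness/score summary.
#'
#' @param ranked a `ranked_answers` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ranked_report <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_answers"))
  recs <- lapply(seq_along(ranked$answers), function(i) {
    a <- ranked$answers[[i]]
    list(
      rank = ranked$table$rank[i],
      node_bindings = as.list(a$node_bindings),
      edges = lapply(ranked$supports[[i]], function(s) {
        list(
          curated_count = s$curated_count, omnicorp_count = s$omnicorp_count,
          support = s$support, weight = s$weight, resistance = s$resistance
        )
      }),
      resistance = ranked$table$resistance[i],
      confidence = ranked$table$confidence[i],
      informativeness = ranked$table$informativeness[i],
      score = ranked$table$score[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.ranked_answers <- function(x, ...) {
  cat(sprintf("<ranked_answers> %d answers\n", length(x$answers)))
  if (nrow(x$table) > 0L) print(utils::head(x$table, 10L))
  invisible(x)
}
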