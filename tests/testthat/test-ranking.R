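# two-node support graph with controllable curated/co-occurrence counts
support_fixture <- function(curated = character(0), cooc = 0L) {
  kg <- mini_kg(
    list("T:S" = "chemical_substance", "T:O" = "disease"),
    list(list("T:S", "associated_with", "T:O", "CTD", curated))
  )
  idx <- if (cooc > 0L) {
    cooc_index_from_pairs(data.frame(a = "T:S", b = "T:O", count = cooc))
  } else {
    cooc_index(data.frame(pmid = character(0), curie = character(0)))
  }
  list(edges = kg$edges, index = idx)
}

test_that("edge support follows the saturating publication-weight model", {
  # no support at all: weight = eps / (eps + k)
  f0 <- support_fixture()
  s0 <- edge_support(f0$edges, f0$index)
  expect_equal(s0$curated_count, 0L)
  expect_equal(s0$omnicorp_count, 0L)
  expect_equal(s0$support, 0)
  expect_equal(s0$weight, 0.01 / 10.01, tolerance = 1e-12)
  expect_equal(s0$weight, 0.000999, tolerance = 1e-3)

  # curated {p1, p2} plus 4 co-occurrences: S = 2 + 0.25*4 = 3
  f1 <- support_fixture(curated = c("p1", "p2"), cooc = 4L)
  s1 <- edge_support(f1$edges, f1$index)
  expect_equal(s1$support, 3.0)
  expect_equal(s1$weight, 3.01 / 13.01, tolerance = 1e-12)
  expect_equal(s1$weight, 0.2314, tolerance = 1e-3)
  expect_equal(s1$resistance, 13.01 / 3.01, tolerance = 1e-12)
})

test_that("edge weight is strictly increasing in each count, resistance decreasing", {
  weights <- vapply(0:20, function(m) {
    f <- support_fixture(cooc = m)
    edge_support(f$edges, f$index)$weight
  }, numeric(1))
  expect_true(all(diff(weights) > 0))
  res <- 1 / weights
  expect_true(all(diff(res) < 0))

  wc <- vapply(0:10, function(m) {
    f <- support_fixture(curated = if (m > 0) sprintf("p%d", 1:m) else character(0))
    edge_support(f$edges, f$index)$weight
  }, numeric(1))
  expect_true(all(diff(wc) > 0))
})

test_that("one curated publication outweighs one co-occurrence publication", {
  for (ncur in 0:5) {
    for (nomni in c(0L, 3L, 17L)) {
      base <- edge_support(
        support_fixture(curated = if (ncur > 0) sprintf("p%d", 1:ncur) else character(0), cooc = nomni)$edges,
        support_fixture(cooc = nomni)$index
      )
      plus_cur <- edge_support(
        support_fixture(curated = sprintf("p%d", 1:(ncur + 1L)), cooc = nomni)$edges,
        support_fixture(cooc = nomni)$index
      )
      plus_omni <- edge_support(
        support_fixture(curated = if (ncur > 0) sprintf("p%d", 1:ncur) else character(0), cooc = nomni)$edges,
        support_fixture(cooc = nomni + 1L)$index
      )
      expect_gte(plus_cur$weight - base$weight, plus_omni$weight - base$weight)
    }
  }
})

test_that("curated counts pool the union of publications across parallel edges", {
  kg <- mini_kg(
    list("T:S" = "gene", "T:O" = "disease"),
    list(
      list("T:S", "associated_with", "T:O", "HETIO", c("p1", "p2")),
      list("T:S", "associated_with", "T:O", "Pharos", c("p2", "p3"))
    )
  )
  s <- edge_support(kg$edges, NULL)
  expect_equal(s$curated_count, 3L) # union {p1, p2, p3}, not 4
})

test_that("effective resistance matches series and parallel closed forms", {
  # series path: 2.0 + 3.0 = 5.0
  expect_equal(
    effective_resistance(c("a", "b", "c"), c("a", "b"), c("b", "c"), c(2, 3), "a", "c"),
    5.0,
    tolerance = 1e-12
  )
  # two parallel branches of 2.0: 1.0
  expect_equal(
    effective_resistance(c("a", "b"), c("a", "a"), c("b", "b"), c(2, 2), "a", "b"),
    1.0,
    tolerance = 1e-12
  )
  # series-parallel combination: 1 + (2 || 2) = 2
  expect_equal(
    effective_resistance(
      c("a", "m", "b"), c("a", "m", "m"), c("m", "b", "b"), c(1, 2, 2), "a", "b"
    ),
    2.0,
    tolerance = 1e-12
  )
  expect_error(
    effective_resistance(c("a", "b", "c"), "a", "b", 1, "a", "c"),
    "not connected"
  )
})

test_that("effective resistance agrees with the direct linear solve on random circuits", {
  for (seed in 1:40) {
    cc <- random_circuit(seed)
    got <- effective_resistance(cc$nodes, cc$from, cc$to, cc$resistance, cc$s, cc$t)
    want <- oracle_resistance(cc$nodes, cc$from, cc$to, cc$resistance, cc$s, cc$t)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("adding a parallel branch never raises resistance (Rayleigh monotonicity)", {
  for (seed in 41:55) {
    cc <- random_circuit(seed)
    base <- effective_resistance(cc$nodes, cc$from, cc$to, cc$resistance, cc$s, cc$t)
    more <- effective_resistance(
      cc$nodes, c(cc$from, cc$s), c(cc$to, cc$t), c(cc$resistance, 5), cc$s, cc$t
    )
    expect_lte(more, base + 1e-12)
    expect_gte(confidence_score(more), confidence_score(base) - 1e-12)
  }
})

test_that("confidence maps resistance monotonically onto (0,1)", {
  expect_equal(confidence_score(1.0), 0.5)
  expect_lt(confidence_score(1e6), 1e-5)
  expect_gt(confidence_score(1e-6), 1 - 1e-5)
  r <- exp(seq(-5, 5, length.out = 50))
  expect_true(all(diff(confidence_score(r)) < 0))
  expect_error(confidence_score(0), "positive")
  expect_error(confidence_score(-1), "positive")
})

test_that("answer resistance of a simple path is the series sum of edge resistances", {
  fx <- make_example_fixture("carbon_monoxide_ms")
  ans <- match_question(fx$kg, fx$question)
  a <- ans[[1L]]
  sup <- lapply(stats::setNames(fx$question$qedges$qeid, fx$question$qedges$qeid), function(qe) {
    eids <- a$edge_bindings[[qe]]
    edge_support(fx$kg$edges[match(eids, fx$kg$edges$eid), , drop = FALSE], fx$index)
  })
  R <- answer_resistance(a, fx$question, sup)
  expect_equal(R, sup[["e0"]]$resistance + sup[["e1"]]$resistance, tolerance = 1e-9)
})

test_that("informativeness spans [0,1] and penalizes generic hubs", {
  # all endpoints at degree 1 -> 1
  kg1 <- mini_kg(
    list("T:A" = "chemical_substance", "T:B" = "disease"),
    list(list("T:A", "associated_with", "T:B"))
  )
  qg <- question_graph(
    qnodes = data.frame(
      qid = c("x", "y"), curie = c("T:A", "T:B"), category = NA_character_,
      stringsAsFactors = FALSE
    ),
    qedges = data.frame(
      qeid = "e", source = "x", target = "y", predicate = NA_character_,
      stringsAsFactors = FALSE
    )
  )
  a1 <- match_question(kg1, qg)[[1L]]
  expect_equal(informativeness_score(a1, qg, kg1), 1.0)

  # triangle: every node at the maximum degree -> 0
  kg2 <- mini_kg(
    list("T:A" = "chemical_substance", "T:B" = "disease", "T:C" = "gene"),
    list(
      list("T:A", "associated_with", "T:B"),
      list("T:B", "associated_with", "T:C"),
      list("T:C", "associated_with", "T:A")
    )
  )
  a2 <- match_question(kg2, qg)[[1L]]
  expect_equal(informativeness_score(a2, qg, kg2), 0.0)

  # swapping an intermediate for a higher-degree node never raises the score
  hub_kg <- mini_kg(
    list(
      "T:CHEM" = "chemical_substance", "T:DIS" = "disease",
      "T:QUIET" = "gene", "T:HUB" = "gene", "T:X1" = "gene", "T:X2" = "gene"
    ),
    list(
      list("T:CHEM", "associated_with", "T:QUIET"),
      list("T:QUIET", "associated_with", "T:DIS"),
      list("T:CHEM", "associated_with", "T:HUB"),
      list("T:HUB", "associated_with", "T:DIS"),
      list("T:HUB", "associated_with", "T:X1"),
      list("T:HUB", "associated_with", "T:X2")
    )
  )
  qg3 <- question_graph(
    qnodes = data.frame(
      qid = c("n0", "n1", "n2"),
      curie = c("T:CHEM", NA, "T:DIS"),
      category = c(NA, "gene", NA), stringsAsFactors = FALSE
    ),
    qedges = data.frame(
      qeid = c("e0", "e1"), source = c("n0", "n1"), target = c("n1", "n2"),
      predicate = NA_character_, stringsAsFactors = FALSE
    )
  )
  ans <- match_question(hub_kg, qg3)
  genes <- vapply(ans, function(a) a$node_bindings[["n1"]], character(1))
  info <- vapply(ans, informativeness_score, numeric(1), qg = qg3, kg = hub_kg)
  expect_gt(info[genes == "T:QUIET"], info[genes == "T:HUB"])
})

test_that("ranking puts the strongly supported TNF answer first on the carbon-monoxide graph", {
  fx <- make_example_fixture("carbon_monoxide_ms", seed = 3L)
  ans <- match_question(fx$kg, fx$question)
  ranked <- rank_answers(ans, fx$question, fx$kg, fx$index)
  expect_equal(ranked$answers[[1L]]$node_bindings[["n1"]], "FIX:TNF")
  expect_equal(ranked$supports[[1L]][["e1"]]$omnicorp_count, 858L)
  expect_equal(ranked$supports[[1L]][["e0"]]$omnicorp_count, 44L)
  expect_true(all(diff(ranked$table$score) <= 0))
  expect_true(all(ranked$table$score > 0 & ranked$table$score <= 1))
  expect_true(all(ranked$table$confidence > 0 & ranked$table$confidence < 1))
  expect_true(all(ranked$table$informativeness >= 0 & ranked$table$informativeness <= 1))
})

test_that("ranking is invariant under permutation of the input answers", {
  fx <- make_example_fixture("ammonia_asthma", seed = 5L)
  ans <- match_question(fx$kg, fx$question)
  r1 <- rank_answers(ans, fx$question, fx$kg, fx$index)
  set.seed(99)
  r2 <- rank_answers(sample(ans), fx$question, fx$kg, fx$index)
  expect_identical(r1$table, r2$table)
})

test_that("answers with identical support and degrees rank lexicographically", {
  kg <- mini_kg(
    list(
      "T:CHEM" = "chemical_substance", "T:DIS" = "disease",
      "T:GA" = "gene", "T:GB" = "gene"
    ),
    list(
      list("T:CHEM", "associated_with", "T:GA"),
      list("T:GA", "associated_with", "T:DIS"),
      list("T:CHEM", "associated_with", "T:GB"),
      list("T:GB", "associated_with", "T:DIS")
    )
  )
  qg <- question_graph(
    qnodes = data.frame(
      qid = c("n0", "n1", "n2"), curie = c("T:CHEM", NA, "T:DIS"),
      category = c(NA, "gene", NA), stringsAsFactors = FALSE
    ),
    qedges = data.frame(
      qeid = c("e0", "e1"), source = c("n0", "n1"), target = c("n1", "n2"),
      predicate = NA_character_, stringsAsFactors = FALSE
    )
  )
  ranked <- rank_answers(match_question(kg, qg), qg, kg, NULL)
  genes <- vapply(ranked$answers, function(a) a$node_bindings[["n1"]], character(1))
  expect_equal(genes, c("T:GA", "T:GB"))
  expect_equal(ranked$table$score[1L], ranked$table$score[2L])
})

test_that("raising an answer's curated support never lowers its rank", {
  build_kg <- function(extra_pubs) {
    mini_kg(
      list(
        "T:CHEM" = "chemical_substance", "T:DIS" = "disease",
        "T:GA" = "gene", "T:GB" = "gene"
      ),
      list(
        list("T:CHEM", "associated_with", "T:GA", "CTD", if (extra_pubs > 0) sprintf("p%d", seq_len(extra_pubs)) else character(0)),
        list("T:GA", "associated_with", "T:DIS", "CTD", c("q1", "q2")),
        list("T:CHEM", "associated_with", "T:GB", "CTD", c("r1", "r2")),
        list("T:GB", "associated_with", "T:DIS", "CTD", c("s1", "s2"))
      )
    )
  }
  qg <- question_graph(
    qnodes = data.frame(
      qid = c("n0", "n1", "n2"), curie = c("T:CHEM", NA, "T:DIS"),
      category = c(NA, "gene", NA), stringsAsFactors = FALSE
    ),
    qedges = data.frame(
      qeid = c("e0", "e1"), source = c("n0", "n1"), target = c("n1", "n2"),
      predicate = NA_character_, stringsAsFactors = FALSE
    )
  )
  rank_of_ga <- vapply(0:6, function(m) {
    kg <- build_kg(m)
    ranked <- rank_answers(match_question(kg, qg), qg, kg, NULL)
    genes <- vapply(ranked$answers, function(a) a$node_bindings[["n1"]], character(1))
    which(genes == "T:GA")
  }, integer(1))
  expect_true(all(diff(rank_of_ga) <= 0))
})

test_that("ranking parameters are validated and loadable from YAML", {
  expect_error(ranking_params(omnicorp_pub_weight = 2), "omnicorp_pub_weight")
  expect_error(ranking_params(combine_gamma = 1.5), "combine_gamma")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("saturation_k: 5\ncombine_gamma: 0.6", f)
  p <- read_ranking_params(f)
  expect_equal(p$saturation_k, 5)
  expect_equal(p$combine_gamma, 0.6)
  expect_equal(p$curated_pub_weight, 1.0)
  writeLines("not_a_param: 1", f)
  expect_error(read_ranking_params(f), "unknown ranking parameter")
})
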