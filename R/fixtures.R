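# Worked-example fixture definitions. Node identifiers use a local FIX
# namespace (identifier authorities are out of scope); publication
# identifiers in these fixtures are synthetic stand-ins. Co-occurrence
# counts marked stated = TRUE are the published counts for the highlighted
# answers; every other count is a deterministic filler draw.

worked_example_defs <- function() {
  list(
    carbon_monoxide_ms = list(
      chemical = c(id = "FIX:CARBON_MONOXIDE", name = "carbon monoxide"),
      disease = c(id = "FIX:MULTIPLE_SCLEROSIS", name = "multiple sclerosis"),
      genes = c("TNF", "BDNF", "IL10", "NGF", "IRF8", "KCNMA1", "CASP8"),
      # gene-disease association carried by two sources; kept as one edge
      # with a compound source token so the fixture stays at 14 edges
      gene_disease_source = c(TNF = "HETIO;Pharos"),
      chem_gene_source = c(TNF = "CTD"),
      chem_gene_curated = list(TNF = "900001"),
      stated_cooc = list(
        chem_gene = c(TNF = 44),
        gene_disease = c(TNF = 858),
        direct = 25
      ),
      # the top-rank claim rides on the highlighted gene's stated counts;
      # fillers must stay strictly below the smallest of them
      top_claim_min_count = 44
    ),
    ammonia_asthma = list(
      chemical = c(id = "FIX:AMMONIA", name = "ammonia"),
      disease = c(id = "FIX:ASTHMA", name = "asthma"),
      genes = c("ADA", "PRKG1", "S100B", "TNF", "MPO", "IL6", "IL1B", "PDE4A", "PARP1"),
      gene_disease_source = c(ADA = "Monarch"),
      chem_gene_source = character(0),
      chem_gene_curated = list(),
      stated_cooc = list(
        chem_gene = numeric(0),
        gene_disease = c(ADA = 32),
        direct = 93
      ),
      top_claim_min_count = NA_real_
    ),
    isopropanol_allergy = list(
      chemical = c(id = "FIX:ISOPROPANOL", name = "isopropanol"),
      disease = c(id = "FIX:ALLERGIC_DISEASE", name = "allergic disease"),
      genes = c("IL6", "TNF", "CSF2"),
      gene_disease_source = c(IL6 = "Pharos"),
      chem_gene_source = c(IL6 = "CTD"),
      chem_gene_curated = list(IL6 = "900002"),
      stated_cooc = list(
        chem_gene = c(IL6 = 2),
        gene_disease = c(IL6 = 79),
        direct = NA_real_
      ),
      top_claim_min_count = NA_real_
    )
  )
}

#' Build a worked-example fixture: graph, co-occurrence index, and question
#'
#' Deterministic generators for three small chemical-gene-disease knowledge
#' graphs, each with its co-occurrence support and the matching three-node
#' mediating-gene question:
#' * `carbon_monoxide_ms` — carbon monoxide, multiple sclerosis, and seven
#'   intermediary genes (TNF, BDNF, IL10, NGF, IRF8, KCNMA1, CASP8);
#' * `ammonia_asthma` — ammonia, asthma, and nine intermediary genes (ADA,
#'   PRKG1, S100B, TNF, MPO, IL6, IL1B, PDE4A, PARP1);
#' * `isopropanol_allergy` — isopropanol, allergic disease, and three
#'   intermediary genes (IL6, TNF, CSF2).
#'
#' Each graph has one chemical-gene and one gene-disease edge per gene. The
#' direct chemical-disease literature link is stored only in the
#' co-occurrence index, never as a graph edge: it is co-occurrence support,
#' not a curated assertion. Published co-occurrence counts are used where
#' known (multiple sclerosis-TNF 858, carbon monoxide-TNF 44, carbon
#' monoxide-multiple sclerosis 25, ammonia-asthma 93, ADA-asthma 32,
#' isopropanol-IL6 2 plus one curated publication, IL6-allergic disease 79);
#' every other count is drawn deterministically from `filler_pub_range`
#' under `seed`. For the carbon-monoxide example the filler maximum must
#' stay strictly below the smallest stated count on the highlighted gene's
#' edges (44), which preserves its top rank. All identifiers live in a
#' local `FIX:` namespace and all fixture PMIDs are synthetic.
#'
#' @param example_id one of `"carbon_monoxide_ms"`, `"ammonia_asthma"`,
#'   `"isopropanol_allergy"`.
#' @param seed integer seed for the filler draws.
#' @param filler_pub_range integer interval (low, high) for unstated
#'   co-occurrence counts.
#' @return list with elements `kg` ([knowledge_graph()]), `index`
#'   (`cooc_index`), `question` ([question_graph()]), and `meta` (a
#'   data.frame of all concept pairs with their counts and a `stated` flag).
#' @export
make_example_fixture <- function(example_id,
                                 seed = 1L,
                                 filler_pub_range = c(5L, 40L)) {
  defs <- worked_example_defs()
  if (!example_id %in% names(defs)) {
    stop(sprintf(
      "unknown example_id '%s'; expected one of: %s",
      example_id, paste(names(defs), collapse = ", ")
    ), call. = FALSE)
  }
  def <- defs[[example_id]]
  stopifnot(
    length(filler_pub_range) == 2L, filler_pub_range[1L] >= 1L,
    filler_pub_range[1L] <= filler_pub_range[2L]
  )
  if (!is.na(def$top_claim_min_count) && filler_pub_range[2L] >= def$top_claim_min_count) {
    stop(sprintf(
      "filler_pub_range must stay strictly below %d, the smallest stated count on the highlighted answer's edges",
      as.integer(def$top_claim_min_count)
    ), call. = FALSE)
  }

  chem_id <- def$chemical[["id"]]
  dis_id <- def$disease[["id"]]
  gene_ids <- paste0("FIX:", def$genes)

  nodes <- data.frame(
    id = c(chem_id, gene_ids, dis_id),
    name = c(def$chemical[["name"]], def$genes, def$disease[["name"]]),
    stringsAsFactors = FALSE
  )
  nodes$categories <- c(
    list("chemical_substance"),
    rep(list("gene"), length(def$genes)),
    list("disease")
  )

  chem_src <- vapply(def$genes, function(g) {
    if (g %in% names(def$chem_gene_source)) def$chem_gene_source[[g]] else "CTD"
  }, character(1))
  dis_src <- vapply(def$genes, function(g) {
    if (g %in% names(def$gene_disease_source)) def$gene_disease_source[[g]] else "Pharos"
  }, character(1))
  chem_pubs <- lapply(def$genes, function(g) {
    if (g %in% names(def$chem_gene_curated)) def$chem_gene_curated[[g]] else character(0)
  })

  edges <- data.frame(
    subject = c(rep(chem_id, length(gene_ids)), gene_ids),
    predicate = "associated_with",
    object = c(gene_ids, rep(dis_id, length(gene_ids))),
    primary_source = c(chem_src, dis_src),
    stringsAsFactors = FALSE
  )
  edges$publications <- c(chem_pubs, rep(list(character(0)), length(gene_ids)))

  kg <- knowledge_graph(nodes, edges)

  # every edge pair plus the direct chemical-disease pair gets a
  # co-occurrence count: stated where published, filler otherwise
  pairs <- data.frame(
    a = c(rep(chem_id, length(gene_ids)), gene_ids, chem_id),
    b = c(gene_ids, rep(dis_id, length(gene_ids)), dis_id),
    kind = c(
      rep("chem_gene", length(gene_ids)),
      rep("gene_disease", length(gene_ids)), "direct"
    ),
    gene = c(def$genes, def$genes, NA),
    stringsAsFactors = FALSE
  )
  stated_for <- function(kind, gene) {
    if (kind == "direct") return(def$stated_cooc$direct)
    v <- def$stated_cooc[[kind]]
    if (!is.null(gene) && !is.na(gene) && gene %in% names(v)) v[[gene]] else NA_real_
  }
  pairs$count <- NA_integer_
  pairs$stated <- FALSE
  fillers <- with_seed(seed, sample(
    seq(filler_pub_range[1L], filler_pub_range[2L]),
    nrow(pairs), replace = TRUE
  ))
  for (i in seq_len(nrow(pairs))) {
    st <- stated_for(pairs$kind[i], pairs$gene[i])
    if (!is.na(st)) {
      pairs$count[i] <- as.integer(st)
      pairs$stated[i] <- TRUE
    } else {
      pairs$count[i] <- fillers[i]
    }
  }

  index <- cooc_index_from_pairs(pairs[, c("a", "b", "count")])

  question <- question_graph(
    qnodes = data.frame(
      qid = c("n0", "n1", "n2"),
      curie = c(chem_id, NA, dis_id),
      category = c("chemical_substance", "gene", "disease"),
      stringsAsFactors = FALSE
    ),
    qedges = data.frame(
      qeid = c("e0", "e1"), source = c("n0", "n1"), target = c("n1", "n2"),
      predicate = NA_character_, stringsAsFactors = FALSE
    )
  )

  list(kg = kg, index = index, question = question, meta = pairs)
}

#' Build a co-occurrence index realizing exact pairwise counts
#'
#' Constructs synthetic PMID postings such that each requested concept pair
#' co-occurs in exactly `count` abstracts and no abstract mentions more
#' than two concepts (so no unrequested pair co-occurs).
#'
#' @param pair_counts data.frame with columns `a`, `b` (CURIEs) and `count`.
#' @return a `cooc_index`.
#' @export
cooc_index_from_pairs <- function(pair_counts) {
  stopifnot(is.data.frame(pair_counts), all(c("a", "b", "count") %in% names(pair_counts)))
  pmids <- character(0)
  curies <- character(0)
  for (i in seq_len(nrow(pair_counts))) {
    m <- pair_counts$count[i]
    if (m <= 0) next
    block <- sprintf("SYN%03d_%04d", i, seq_len(m))
    pmids <- c(pmids, block, block)
    curies <- c(curies, rep(pair_counts$a[i], m), rep(pair_counts$b[i], m))
  }
  cooc_index(data.frame(pmid = pmids, curie = curies, stringsAsFactors = FALSE))
}

#' Generate a seeded random typed knowledge graph
#'
#' Node categories are drawn from the miniature ontology's leaf categories;
#' edges are distinct (endpoint pair, predicate) combinations with random
#' orientation, source, and 0-3 synthetic curated publications. Pure
#' function of its arguments.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param n_edges number of edges; must not exceed
#'   `choose(n_nodes, 2) * length(predicates)`.
#' @param seed integer seed.
#' @param predicates candidate predicate tokens.
#' @return a [knowledge_graph()].
#' @export
make_random_kg <- function(n_nodes, n_edges, seed,
                           predicates = c("associated_with", "affects")) {
  stopifnot(n_nodes >= 1L, n_edges >= 0L)
  max_edges <- choose(n_nodes, 2L) * length(predicates)
  if (n_edges > max_edges) {
    stop(sprintf(
      "n_edges = %d infeasible: at most %d distinct (pair, predicate) edges for %d nodes",
      n_edges, max_edges, n_nodes
    ), call. = FALSE)
  }
  ont <- default_ontology()
  leaves <- setdiff(ont$categories, ont$root)
  with_seed(seed, {
    ids <- sprintf("FIX:N%03d", seq_len(n_nodes))
    nodes <- data.frame(id = ids, name = paste("node", seq_len(n_nodes)), stringsAsFactors = FALSE)
    nodes$categories <- as.list(sample(leaves, n_nodes, replace = TRUE))

    if (n_edges > 0L) {
      all_pairs <- utils::combn(ids, 2L)
      cand <- expand.grid(
        pair = seq_len(ncol(all_pairs)), predicate = predicates,
        stringsAsFactors = FALSE
      )
      pick <- cand[sample.int(nrow(cand), n_edges), , drop = FALSE]
      flip <- sample(c(TRUE, FALSE), n_edges, replace = TRUE)
      subj <- ifelse(flip, all_pairs[2L, pick$pair], all_pairs[1L, pick$pair])
      obj <- ifelse(flip, all_pairs[1L, pick$pair], all_pairs[2L, pick$pair])
      npub <- sample(0:3, n_edges, replace = TRUE)
      edges <- data.frame(
        subject = subj, predicate = pick$predicate, object = obj,
        primary_source = sample(c("CTD", "HETIO", "Pharos", "Monarch"), n_edges, replace = TRUE),
        stringsAsFactors = FALSE
      )
      edges$publications <- lapply(seq_len(n_edges), function(i) {
        if (npub[i] == 0L) character(0) else sprintf("RP%03d_%d", i, seq_len(npub[i]))
      })
    } else {
      edges <- data.frame(
        subject = character(0), predicate = character(0), object = character(0),
        primary_source = character(0), stringsAsFactors = FALSE
      )
      edges$publications <- list()
    }
    knowledge_graph(nodes, edges, ont)
  })
}

#' Generate a synthetic survey cohort with planted exposure-outcome effects
#'
#' Subjects are drawn independently. Exposures are Bernoulli at
#' `exposure_prev`. Each outcome follows a logistic model: baseline odds
#' from `outcome_prev`, shifted by `log(odds_ratio)` for each planted
#' (exposure, outcome, odds_ratio) effect when the subject is exposed, so
#' the exposed/unexposed odds ratio equals the planted value exactly.
#' Non-planted pairs are independent. Missingness is completely at random
#' at `missing_rate`, applied cell-wise to exposures and outcomes. Pure
#' function of its arguments.
#'
#' @param n number of subjects.
#' @param exposures character vector of chemical labels.
#' @param outcomes character vector of condition labels.
#' @param planted optional data.frame with columns `exposure`, `outcome`,
#'   `odds_ratio` (all odds ratios > 0).
#' @param exposure_prev exposure prevalence in \[0,1\] (recycled).
#' @param outcome_prev baseline outcome prevalence in \[0,1\] (recycled).
#' @param missing_rate cell-wise missingness rate in \[0,1\].
#' @param seed integer seed.
#' @param classes named list of chemical classes (passed to [cohort()]).
#' @return a [cohort()].
#' @export
make_synthetic_cohort <- function(n, exposures, outcomes,
                                  planted = NULL,
                                  exposure_prev = 0.2,
                                  outcome_prev = 0.1,
                                  missing_rate = 0,
                                  seed = 1L,
                                  classes = list()) {
  stopifnot(
    n >= 1L, length(exposures) >= 1L, length(outcomes) >= 1L,
    all(exposure_prev >= 0 & exposure_prev <= 1),
    all(outcome_prev >= 0 & outcome_prev <= 1),
    missing_rate >= 0, missing_rate <= 1
  )
  if (!is.null(planted)) {
    stopifnot(
      is.data.frame(planted),
      all(c("exposure", "outcome", "odds_ratio") %in% names(planted)),
      all(planted$odds_ratio > 0),
      all(planted$exposure %in% exposures), all(planted$outcome %in% outcomes)
    )
  }
  eprev <- rep_len(exposure_prev, length(exposures))
  oprev <- rep_len(outcome_prev, length(outcomes))

  with_seed(seed, {
    subjects <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)), stringsAsFactors = FALSE
    )
    for (j in seq_along(exposures)) {
      subjects[[exposures[j]]] <- stats::rbinom(n, 1L, eprev[j])
    }
    for (j in seq_along(outcomes)) {
      eta <- rep(stats::qlogis(oprev[j]), n)
      if (!is.null(planted)) {
        rel <- planted[planted$outcome == outcomes[j], , drop = FALSE]
        for (r in seq_len(nrow(rel))) {
          eta <- eta + log(rel$odds_ratio[r]) * subjects[[rel$exposure[r]]]
        }
      }
      subjects[[outcomes[j]]] <- stats::rbinom(n, 1L, stats::plogis(eta))
    }
    if (missing_rate > 0) {
      for (col in c(exposures, outcomes)) {
        drop_mask <- stats::runif(n) < missing_rate
        subjects[[col]][drop_mask] <- NA_integer_
      }
    }
    cohort(subjects, exposures, outcomes, classes)
  })
}
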