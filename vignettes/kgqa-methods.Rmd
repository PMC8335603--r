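---
title: "Answer ranking and association screening in kgqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Answer ranking and association screening in kgqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgqa)
```

## What the package models

`kgqa` is a desk-scale re-creation of a knowledge-graph question-answering
workflow for environmental health: a survey cohort suggests statistical
associations between workplace chemical exposures and immune-mediated
diseases, and a typed biomedical knowledge graph is then queried for
*mechanistic* support — which genes could plausibly mediate an observed
chemical–disease association? The pipeline has four stages:

1. **Association screen.** Every (chemical, outcome) and (chemical class,
   outcome) pair in a cohort is tested on its 2×2 table; significant hits
   become candidate associations.
2. **Question generation.** Each hit becomes a three-node question graph:
   a pinned chemical, a type-constrained gene, a pinned disease.
3. **Subgraph matching.** The question is matched exhaustively against a
   typed property graph; each matching chemical–gene–disease path is an
   answer.
4. **Answer ranking.** Answers are scored by the publication support of
   their edges (curated sources plus literature co-occurrence), combined
   through an electrical-resistance analogy and a specificity
   ("informativeness") score.

## The graph model

Nodes are CURIE-identified entities carrying one or more categories from a
miniature upper-level ontology (`chemical_substance`, `gene`, `disease`,
`phenotypic_feature` under a universal `named_thing`). Edges are directed
assertions `subject –predicate→ object` with a primary source and a list of
curated publications, but degree and matching treat them as undirected: an
answer path is traversed without regard to assertion direction, mirroring
how such assertions are displayed to users. Parallel edges (same endpoints,
different predicate or source) are kept distinct on load and merged only at
ranking time, because real integrations record the same biological link
from several sources.

Matching is an exact backtracking search, most-constrained question node
first, with two semantic commitments:

* **Injectivity.** Distinct question nodes bind distinct graph nodes; a
  chemical–gene–disease path whose "gene" is the disease itself is
  meaningless.
* **Witness collapse.** All parallel edges consistent with a question edge
  are collected into one answer's edge bindings. Multiple sources
  strengthen an answer; they do not multiply it.

On graphs of up to a few thousand nodes this needs no indexes; the test
suite proves the matcher equal to brute-force enumeration over all
injective assignments on hundreds of random graphs (≤ 20 nodes, 2–4
question nodes), which is where exhaustive enumeration is still feasible.

## Edge weights, resistance, and confidence

Each bound question edge receives a publication support

$$S = w_c \, N_{\text{curated}} + w_o \, N_{\text{cooc}},$$

where $N_{\text{curated}}$ is the size of the union of curated publication
lists over the parallel witness edges and $N_{\text{cooc}}$ is the number
of abstracts in which the two endpoint concepts co-occur. Defaults
$w_c = 1$, $w_o = 0.25$ encode that a curated assertion's publication is
worth more than a raw co-occurrence; any $w_o \le w_c$ preserves that
ordering, and the tests check it count-by-count. Support maps to a weight
in $(0,1)$ by the saturating form

$$w = \frac{S + \varepsilon}{S + \varepsilon + k},
\qquad \varepsilon = 0.01,\; k = 10,$$

so an edge's electrical resistance $R = 1/w$ is always finite and
positive: $k$ is the (weighted) publication count at which an edge reaches
weight 1/2, and $\varepsilon$ keeps entirely unsupported edges conductive
rather than infinite. The saturation means the difference between 800 and
900 publications matters much less than between 0 and 10, which is the
intended reading of "more evidence, higher rank" without letting a single
enormous literature dominate everything.

An answer's resistance is the two-terminal effective resistance of its
bound circuit — branch per question edge, computed from the Moore–Penrose
pseudoinverse of the weighted Laplacian, $R_{\mathrm{eff}} =
(e_s - e_t)^\top L^+ (e_s - e_t)$. For the common linear
chemical–gene–disease question this is simply the series sum of the two
edge resistances; parallel branches add conductances, so independent lines
of evidence lower resistance (Rayleigh monotonicity — verified in tests
against an independent linear solve). The terminals are the two pinned
question nodes; when a question does not pin exactly two nodes we fall
back to the mean pairwise effective resistance over all pinned pairs (over
all pairs if fewer than two are pinned), which reduces to the natural
definition in every case the pipeline generates. An answer to a one-node
question has no circuit; its resistance is defined as 1 so that its
confidence is exactly 1/2 ("no path evidence either way").

Confidence is $c = 1/(1+R)$: a strictly decreasing map of $(0,\infty)$
onto $(0,1)$ with unit resistance at 1/2. Only the ordering of confidences
matters downstream; the production system whose behaviour this package
emulates does not publish its numeric scores, so absolute values here are
package-defined and the tests assert ordering properties, not score
values.

## Informativeness

Answers that route through generic hubs (a gene connected to everything)
are less informative than answers through specific nodes. Per bound edge
we take

$$1 - \frac{\log d(s) + \log d(o)}{2 \log \Delta},$$

with $d$ the endpoint's degree in the *full* graph and $\Delta$ the
graph's maximum degree (clamped to at least 2), and average over the
answer's edges. Endpoints all at degree 1 give 1; endpoints at the maximum
degree give 0. Degree is the graph-intrinsic proxy for "generic"; no
external ontology depth is needed. The final score is the weighted
geometric mean

$$\text{score} = c^{\gamma} \cdot i^{1-\gamma}, \qquad \gamma = 0.8,$$

confidence-dominant because informativeness is meant to *modulate*
confidence, not compete with it. A zero informativeness is floored at
$\varepsilon$ before combining so the score stays positive. Ties are broken
lexicographically on the sorted bound CURIEs; the ranking is therefore a
deterministic, permutation-invariant function of the inputs. All constants
live in `ranking_params()` and can be overridden from a YAML config.

## Literature co-occurrence

The co-occurrence index links PMIDs to concepts by dictionary annotation:
titles and abstracts are concatenated, lowercased, split on token
boundaries, and scanned greedily longest-match-first against a term→CURIE
lexicon ("carbon monoxide" consumes its tokens, suppressing the inner
"carbon"; "ada" cannot fire inside "adaptation"). This stands in for a
full named-entity-recognition service while preserving the one contract
the ranking needs: a set of (PMID, concept) links supporting pairwise
co-occurrence counts. At most one link is stored per abstract and concept.
Deduplication, symmetry, and equality with a quadratic re-scan are tested
on random corpora.

## The association screen

For each exposure–outcome pair a 2×2 table is built with pairwise deletion
of missing responses; a class-level exposure is positive if *any* member
chemical is positive, missing only when no member is positive and at least
one is missing. The test is Pearson's chi-square (no continuity
correction) unless Cochran's rule fires — any expected cell below 5, or an
empty margin — in which case the two-sided Fisher exact test is used. All
non-degenerate tests in a screen form a single Benjamini–Hochberg family
(chemical- and class-level pooled), with significance flagged at adjusted
p < .05 and < .10. Odds ratios are Wald with a 1.96 normal quantile,
reported as undefined when any cell is zero, and deliberately unadjusted:
no small-sample correction, no covariates, matching the exploratory survey
analysis the screen emulates. The choice of the uncorrected Pearson
statistic, the Cochran trigger, and the single pooled FDR family are
package conventions where the emulated analysis left the details
unstated.

Two statistical caveats worth knowing: the two-sided Fisher p-value is a
step function, so it approaches the chi-square p-value only like the
largest single-table probability (roughly $1/\sqrt{n}$ — the suite checks
agreement within 0.02 at cell counts in the thousands, where that bound
actually holds); and BH adjustment is not idempotent, so adjusted p-values
must never be re-adjusted.

## Synthetic data: what it emulates and what it does not

All inputs are generated in code; nothing is downloaded.

* **Worked-example graphs** (`make_example_fixture()`) encode three small
  chemical–gene–disease neighbourhoods — carbon monoxide/multiple
  sclerosis with seven intermediary genes, ammonia/asthma with nine,
  isopropanol/allergic disease with three — with one chemical–gene and one
  gene–disease edge per gene. Published co-occurrence counts are used
  where known (858 for multiple sclerosis–TNF, 44 for carbon
  monoxide–TNF, 25 for the direct carbon monoxide–multiple sclerosis
  pair, 93 for ammonia–asthma, 32 for ADA–asthma, 2 for isopropanol–IL6
  plus one curated publication, 79 for IL6–allergic disease); every other
  count is a seeded draw from `filler_pub_range` (default 5–40). For the
  carbon-monoxide example the filler maximum is validated to stay strictly
  below 44, the smallest published count on the highlighted gene's edges,
  which is what preserves TNF's top rank. The direct chemical–disease
  literature link lives only in the co-occurrence index — it is
  co-occurrence support, not a curated assertion, so it is not a graph
  edge. All identifiers use a local `FIX:` namespace and all PMIDs in
  fixtures are synthetic.
* **Random graphs** (`make_random_kg()`) are seeded draws of distinct
  (endpoint pair, predicate) combinations used by the property suites.
* **Synthetic cohorts** (`make_synthetic_cohort()`) draw independent
  subjects with Bernoulli exposures (default prevalence 0.2) and logistic
  outcomes (default baseline prevalence 0.1), so a planted effect's
  exposed/unexposed odds ratio equals the requested value exactly;
  missingness is completely at random. The default shape mirrors the
  emulated survey: 4574 subjects, 18 chemical classes, binary self-report.

What the generators deliberately do not emulate: correlated exposures,
confounding (age, sex, race), misclassification of self-report, informative
missingness, and real identifier namespaces. Passing tests therefore
demonstrate correctness of the machinery under clean conditions, not
robustness to survey biases.

## Verification at desk scale

The test suite sizes are choices, not measurements of anything external:
matcher-vs-oracle on 100 random graphs of up to 20 nodes; resistance
against an independent linear solve on circuits of up to 6 nodes
(tolerance 1e-9); Wald CI coverage of a planted odds ratio 2.0 in 200
cohorts of n = 2000 (accepted range 91–99%); 100 null screens of 18
chemicals × 17 outcomes at n = 1000 with at most 10% of replicates showing
any false FDR-.05 hit; planted-effect recovery at the survey's n = 4574.

Not reproducible at this scale, and intentionally out of scope: the
production knowledge graph (millions of nodes, hundreds of millions of
edges), the emulated survey's actual 45/20 significant-association counts
and its published per-association OR/CI/p values (the cohort data are not
public — these are covered only by the property-based suites above), and
the production system's numeric answer scores (unpublished; only ordering
is testable). One published inconsistency is knowingly left alone: the
carbon monoxide–multiple sclerosis odds ratio 6.4583 is not the geometric
mean of its published interval (1.8524, 18.2844), so that interval cannot
have been a pure Wald interval; this package implements the Wald
convention and makes no attempt to reverse-engineer that row.

## Worked example

```{r example}
fx <- make_example_fixture("carbon_monoxide_ms", seed = 1)
answers <- match_question(fx$kg, fx$question)
length(answers)

ranked <- rank_answers(answers, fx$question, fx$kg, fx$index)
ranked$table[, c("rank", "bindings", "resistance", "confidence", "score")]
```

The TNF answer leads because its two edges carry far more literature
support (44 and 858 co-occurring abstracts, plus a curated publication)
than any filler edge, hence lower resistance and higher confidence; the
informativeness term is constant across these answers because every
intermediary gene has the same degree in this small graph.
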