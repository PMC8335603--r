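# kgqa

Knowledge-graph question answering for exposure–disease hypothesis
generation, at desk scale.

Environmental-health surveys routinely surface statistical associations —
say, between self-reported workplace exposure to carbon monoxide and
multiple sclerosis — that carry no mechanistic explanation. `kgqa`
implements the full loop that turns such associations into ranked
mechanistic hypotheses:

1. **screen** a cohort of binary exposure/outcome responses: a 2×2 table
   per (chemical, outcome) and (chemical class, outcome) pair, Pearson
   chi-square or two-sided Fisher exact test chosen by Cochran's rule, one
   Benjamini–Hochberg FDR family, Wald odds ratios
   `exp(ln(ad/bc) ± 1.96·√(1/a+1/b+1/c+1/d))`;
2. **generate** a question graph per significant hit: *pinned chemical —
   gene — pinned disease*;
3. **match** the question exhaustively against a typed property graph
   (CURIE-identified nodes, category subsumption under a miniature
   upper-level ontology, provenance-bearing edges) — every injective,
   type-consistent assignment witnessed by graph edges is an answer
   subgraph;
4. **rank** the answers. Each bound edge gets publication support
   `S = N_curated + 0.25·N_cooc` (curated sources outweigh raw literature
   co-occurrence), weight `w = (S+ε)/(S+ε+k)`, and resistance `1/w`; an
   answer's confidence is `1/(1+R_eff)` with `R_eff` the two-terminal
   effective resistance of its bound circuit (Laplacian pseudoinverse;
   series sum for a simple path), and the final score is
   `confidence^0.8 · informativeness^0.2`, where informativeness is a
   degree-based specificity `1 − (log d(s)+log d(o))/(2·log Δ)` averaged
   over the answer's edges.

Literature co-occurrence comes from a small abstract-level index:
dictionary annotation (greedy longest match on token boundaries) of
abstract records against a term→CURIE lexicon, supporting pairwise
abstract co-occurrence counts. Deterministic generators supply every input:
three worked-example graphs (carbon monoxide–multiple sclerosis, seven
intermediary genes; ammonia–asthma, nine; isopropanol–allergic disease,
three), seeded random graphs, and synthetic cohorts with exactly planted
odds ratios. See `vignettes/kgqa-methods.Rmd` for the model details and
the reasoning behind every constant.

## Worked example

```r
library(kgqa)

fx <- make_example_fixture("carbon_monoxide_ms", seed = 1)
answers <- match_question(fx$kg, fx$question)
length(answers)
#> [1] 7

ranked <- rank_answers(answers, fx$question, fx$kg, fx$index)
ranked$table[, c("rank", "bindings", "confidence", "informativeness", "score")]
#>   rank                                              bindings confidence informativeness  score
#> 1    1    FIX:CARBON_MONOXIDE|FIX:MULTIPLE_SCLEROSIS|FIX:TNF    0.25778          0.3219 0.2695
#> 2    2  FIX:CARBON_MONOXIDE|FIX:CASP8|FIX:MULTIPLE_SCLEROSIS    0.17614          0.3219 0.1987
#> 3    3   FIX:CARBON_MONOXIDE|FIX:IL10|FIX:MULTIPLE_SCLEROSIS    0.14492          0.3219 0.1700
#> 4    4 FIX:CARBON_MONOXIDE|FIX:KCNMA1|FIX:MULTIPLE_SCLEROSIS    0.14460          0.3219 0.1697
#> 5    5    FIX:CARBON_MONOXIDE|FIX:MULTIPLE_SCLEROSIS|FIX:NGF    0.12342          0.3219 0.1495
#> 6    6   FIX:CARBON_MONOXIDE|FIX:IRF8|FIX:MULTIPLE_SCLEROSIS    0.12070          0.3219 0.1469
#> 7    7   FIX:BDNF|FIX:CARBON_MONOXIDE|FIX:MULTIPLE_SCLEROSIS    0.07978          0.3219 0.1055
```

The carbon monoxide–gene–multiple sclerosis question has exactly seven
answers, one per intermediary gene. TNF ranks first because its two edges
carry 44 and 858 co-occurring abstracts (plus one curated publication)
against filler counts of at most 40 elsewhere: more publications → higher
edge weight → lower path resistance → higher confidence. Informativeness
is constant here because every gene has the same degree in this small
graph.

The upstream screen that motivates the question:

```r
ch <- make_synthetic_cohort(
  n = 4574,
  exposures = c("carbon monoxide", "benzene"),
  outcomes  = c("multiple sclerosis", "asthma"),
  planted   = data.frame(exposure = "carbon monoxide",
                         outcome = "multiple sclerosis", odds_ratio = 6),
  seed = 17
)
screen_associations(ch)[, c("exposure", "outcome", "test", "p_fdr", "or", "sig05")]
#>          exposure            outcome       test     p_fdr    or sig05
#> 1 carbon monoxide multiple sclerosis chi_square 6.25e-104 5.930  TRUE
#> 2 carbon monoxide             asthma chi_square  4.27e-01 0.895 FALSE
#> 3         benzene multiple sclerosis chi_square  4.27e-01 0.912 FALSE
#> 4         benzene             asthma chi_square  4.27e-01 1.100 FALSE
```

Only the planted pair survives FDR correction, with an estimated odds
ratio of 5.93 against the planted 6. `questions_from_hits()` then emits
the corresponding question graph, and `match_question()`/`rank_answers()`
close the loop — or run the whole chain from a shell via the bundled
script:

```sh
Rscript inst/cli/kgqa fixtures --example carbon_monoxide_ms --out fx
Rscript inst/cli/kgqa ask --nodes fx/nodes.tsv --edges fx/edges.tsv \
    --question fx/question.yaml --out answers
```

Subcommands: `fixtures`, `index`, `ask`, `rank`, `screen`, `hypothesize`,
`export-cypher` (the last writes the graph as Cypher CREATE statements for
a Neo4j-style store).

## Limitations

The production-scale system this package emulates (millions of nodes,
live literature indexing, a web UI) is out of scope, as are the emulated
survey's actual association tables — the cohort data are not public, so
the screen is validated on synthetic cohorts with planted effects
instead. Identifiers live in a local `FIX:` namespace; fixture PMIDs are
synthetic.
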