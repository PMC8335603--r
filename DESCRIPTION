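Package: kgqa
Title: Knowledge-Graph Question Answering for Exposure-Disease Hypothesis Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale biomedical knowledge-graph question-answering
    toolkit. Provides a typed property-graph store with category
    subsumption and KGX-style TSV input/output, exhaustive answer-subgraph
    matching against small question graphs (meta-graphs), a literature
    co-occurrence index built by dictionary annotation of abstract
    corpora, answer ranking that treats publication-weighted edges as
    electrical conductances and scores answers by two-terminal effective
    resistance combined with a degree-based informativeness score, and an
    exposure-outcome association screen (chi-square/Fisher selection,
    Benjamini-Hochberg false discovery rate correction, Wald odds ratios)
    that turns significant hits into chemical-gene-disease question
    graphs. Deterministic fixture generators supply worked-example graphs,
    random graphs, synthetic corpora, and synthetic cohorts with planted
    odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    MASS
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
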