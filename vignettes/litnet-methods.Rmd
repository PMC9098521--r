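---
title: "litnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{litnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

## The model

litnet treats a corpus of annotated abstracts as a bipartite
document–entity incidence structure and derives everything from it. The
co-occurrence assumption is the usual one in literature-based discovery:
bioentities annotated in the same abstract are taken to be biologically or
chemically related. The scope of "same" is the whole document
(title + abstract) — sentence-level windows are deliberately out of scope
because abstract-level annotation exports carry no reliable sub-document
structure.

For a document set $D$ and entity $u$, let $D_u \subseteq D$ be the
documents mentioning $u$ (after identifier normalization and per-document
deduplication). The co-occurrence network has

* node weight $\mathrm{doc\_count}(u) = |D_u|$,
* an edge $\{u, v\}$ iff $D_u \cap D_v \neq \emptyset$, with weight
  $w(u,v) = |D_u \cap D_v|$ and the pmid set itself stored on the edge.

Keeping the supporting pmid *sets* (not just counts) is a deliberate design
choice: network set operations then recompute weights exactly from united
pmid sets instead of summing counts, which would double-count documents
matched by two overlapping queries. The cost is memory proportional to
total incidence, negligible at corpus sizes this package targets.

Self-loops are excluded: at document scope an entity trivially co-occurs
with itself, which carries no information.

## Identifier normalization

Annotation identifier fields are messy: composite values joined by `;` or
`|`, an optional case-varying `MESH:` prefix, and `-` for "no identifier".
`normalize_identifier()` is total — it never errors. Rules, in order:
split composites, strip the prefix, then type by shape and class (bare
integer + Species → TaxID; `[CD]\d{6,9}` + Chemical/Disease → MeSH UI).
Anything else is kept under namespace `other` and flagged rather than
dropped, so unexpected vocabularies (cell-line registries, gene ids)
survive into QC reports without polluting the taxonomy/MeSH pipelines.
Unidentified mentions (`-`) are excluded from networks but counted in the
QC report.

## Query semantics

The query language mirrors PubMed surface syntax: `AND`, `OR`, `NOT`
(case-insensitive, standalone tokens), quoted phrases, trailing-`*`
truncation, parentheses, and implicit `AND` for bare adjacency. Precedence
is `NOT` > `AND` > `OR`, all binary and left-associative. Two decisions the
syntax source is silent on:

* **`NOT` is binary** (`a NOT b` = matches of `a` minus matches of `b`),
  as in PubMed. A leading `NOT` is a parse error: unary negation over an
  open-ended corpus is ill-defined.
* **Tokenization** splits on every non-alphanumeric character and
  case-folds, so `anti-inflammatory` becomes two tokens and a bare
  hyphenated query word is parsed as a phrase. One tokenizer is shared by
  parsing and evaluation, which is what makes the phrase/term equivalence
  (`"skin"` ≡ `skin`) hold exactly. A truncated term must be a single
  token after tokenization; `anti-inflam*` is rejected rather than given
  surprising semantics.

Evaluation is local and set-based (per-node pmid sets combined with
∩/∪/∖). The test suite checks it against an independent per-document
recursive matcher on 100 random ASTs.

## Hierarchies

**Taxonomy.** The induced subtree over a hit set is the minimal
ancestor-closed tree: root ∪ hits ∪ every ancestor on a hit→root path.
Internal hits are allowed (a genus can itself be a hit). The default root
is the loaded taxonomy's own root — for a real NCBI dump the natural choice
is the 'cellular organisms' node (TaxID 131567), but that constant is
configuration, never hard-coded, because fixtures define their own roots.
Rank strings are carried as metadata and never enforced: real NCBI ranks
are irregular ("no rank", clade ranks), so any logic keyed on rank equality
(see recommendations) must tolerate hits with no anchor.

**MeSH.** Node identity in the MeSH forest is the *tree number*, not the
descriptor UI: a descriptor occupying $k$ eligible positions contributes
$k$ nodes, which matches how tree-structure browsers display the
hierarchy and how multi-rooted descriptors behave in practice. Ancestor
positions are materialized by truncating dotted codes; positions not owned
by any loaded descriptor get the tree number itself as label. Branches are
restricted to configurable top-level letters (default `C` and `D`,
diseases and chemicals/drugs) and united under per-letter category roots
plus one synthetic `MeSH` root, so the output is always a single tree and
`edges = nodes − 1` holds.

**Determinism.** Children are ordered lexicographically by node id
everywhere; serialization (indented text, JSON, GEXF) is byte-stable given
equal inputs. Every ordering question the source formats leave open is
resolved this way: reproducible diffs beat aesthetic orderings.

## Similarity and set operations

Similarity between a query network and a reference network is computed on
node-id sets only: `tp` = common nodes, from which precision, recall, F1
and Jaccard follow. Beyond "true positives = common nodes", the exact
metric set is a reconstruction (the original supplementary material is not
part of this package's inputs) and is flagged as such. Zero denominators
yield 0; comparing two empty networks yields `NA` for every ratio with an
`undefined` flag, because silently reporting 0 or 1 there would be a
statement the data cannot support.

Intersection keeps only edges present in *both* networks (strict). For the
display-style "shared nodes highlighted on the union" view,
`highlight_common()` is provided separately — both exist because both
behaviours are legitimately wanted in different contexts.

## Recommendations

`recommend_allied()` generalizes a manually-performed analysis into a rule:
for every distinct ancestor of the requested rank (default genus; family is
the other documented choice, hence rank is a parameter) above any hit
species, recommend the resolved reference-list species under that anchor
that are not hits. The anchor is the *nearest strict ancestor* with the
exact rank string; hits without one are skipped and reported. Name
resolution is exact, case-insensitive scientific-name matching only —
fuzzy matching and synonym tables are out of scope, and ambiguous names
(one name, several taxids) are left unresolved rather than guessed.

## The synthetic world

The fixture generator emulates the *shape* of an annotated abstract slice,
not its language:

* **200 documents, 50 entities** (6 genera × 5 species + 20 MeSH
  descriptors) by default — large enough that co-occurrence, closure and
  set-operation edge cases (shared edges, multi-component graphs,
  duplicate annotations) all occur, small enough for exact brute-force
  oracles in seconds.
* 2–6 entity mentions per document, sampled *with replacement* so
  per-document deduplication is exercised; ~10% of documents additionally
  carry an exactly duplicated annotation row.
* Query keywords are planted with each term always followed by a filler
  word, so the only contiguous keyword pair in the whole corpus is the
  deliberately planted phrase — phrase queries have provable answers.
* Offsets are exact by construction; a lenient-mode fixture with drifted
  offsets is created ad hoc in tests rather than generated.
* Taxids (9,000,000+) and UIs (`D9xxxxxx`) come from a reserved synthetic
  range so documentation examples can never be mistaken for real entities.

What a green test therefore establishes: structural and algebraic
correctness against independent oracles. What it does not establish:
behaviour on real annotator error modes (systematically drifted offsets,
identifier vocabulary drift between annotator and ontology dumps),
real-scale performance, or any biological claim. Hits absent from a loaded
ontology are consequently never fatal — live annotation ids can postdate a
dump — they go to skipped-id reports.

Each generator call seeds its own RNG scope and restores the caller's
stream, so fixtures are byte-identical per seed and never perturb user
code.

## Numerical and degenerate-input choices

* density = $2E/(N(N-1))$ for $N \ge 2$, else 0; empty network → all-zero
  stats with 0 components.
* weight = |pmids| is validated on every network constructor; networks
  re-imported from GEXF have unknown provenance (`pmids = NULL`) and are
  exempt from that check while keeping file weights.
* GEXF is written as 1.2draft, undirected, with typed attvalues; directed
  files are rejected on import. Edge pmid sets are documented as lossy in
  both graph formats.
* All text I/O is UTF-8 with line endings normalized on read and `\n` on
  write; writers emit bytes directly so output is platform-independent.

## Known limitations

Full-text (body) offsets, BioC XML, taxonomy merge/deletion files, MeSH
qualifiers and supplementary concept records, field-tagged queries, edge
significance testing and any layout computation are out of scope. The
gene/mutation/cell-line classes are parsed and indexable but no hierarchy
builder consumes them — their ontologies are not loaded by this package.
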