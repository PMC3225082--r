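---
title: "Evidence-path inference: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-path inference: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evipath)
```

## The model

`evipath` treats aggregated chemogenomic evidence about one query compound as
a knowledge graph: a *set* of subject–predicate–object statements over a
small fixed ontology (classes `ChemicalCompound`, `BioAssay`,
`JournalArticle`, `Gene`, `Disease`; typed properties such as `isSimilarTo`,
`isActiveIn`, `isContainedIn`, `hasGene`, `isAssociatedWith`,
`hasSimilarity`). New compound–disease links are *derived*, not asserted:
a rule base of body → head triple-pattern rewrites is forward-chained to
fixpoint, and each firing is kept as an **evidence path** — the rule id, the
full body-variable binding, and the grounded body triples.

Two modelling commitments matter throughout:

* **Set semantics.** Adding a statement twice is a no-op. Counting therefore
  happens at the level of *paths*, not triples: two articles that support the
  same gene–disease edge through different similar compounds are two paths
  even though they ultimately derive the same head triple. Path identity is
  the pair (rule id, body-variable binding).
* **Provenance is first-class.** A ranked association is only as useful as
  the chain behind it, so every path retains its grounded body, and the JSON
  export carries the supporting compound, its verbatim similarity string, the
  intermediate gene/assay/article, and any `isInferredFrom` publication ids.

### Ranking

Paths are clustered by the disease named in their inferred head and clusters
are ranked. Two metrics are exposed:

* `path_count` (default): the number of evidence paths in the cluster. This
  is the intended ranking — more independent chains of evidence, stronger
  association.
* `property_count`: the literal aggregate — the number of (predicate,
  object) statements whose *subject* is the disease node in the materialized
  graph, including housekeeping statements such as `rdf:type` and
  `isInferredFrom`. It is provided because it is the historically specified
  query, but it under-counts: under set semantics, paths that share a
  gene–disease triple collapse to one statement. The worked example makes
  the two metrics disagree (two lymphoma paths, one lymphoma subject
  statement), and the test suite pins that case.

Ties are broken lexicographically on the disease identifier; ranks are
1..N without gaps. This tie-break is arbitrary but stable, which the tests
rely on.

## The rule base

Three rules are kept verbatim from the published listing (tagged
`provenance_tag = "paper"`). Two of their quirks are preserved deliberately:

* **Rule 3 is unanchored.** As printed it starts at `?CompoundID` with no
  `isSimilarTo` link, so it fires for *any* compound with bioassay activity.
  In practice ingested graphs contain only the query compound's similar
  compounds, so the firings are meaningful; the reconstructed rule `r5` is
  the query-anchored variant. On the worked example both fire, which is why
  the lymphoma cluster holds two paths.
* **Rule 1 expects `bioassay isAssociatedWith disease`.** The ingest stage
  emits exactly that statement when a disease term occurs in an assay
  description without a gene intermediary, so the verbatim rule is
  executable.

The remaining five rules (`r4`–`r8`) reconstruct the evidence channels the
published listing describes but does not print: direct curated
compound–disease records (`r4`), the anchored bioassay–gene chain (`r5`),
literature gene/compound co-occurrence via `isrelatedTo` (`r6`), direct
target annotations (`r7`), and article–disease mentions (`r8`). They are
tagged `reconstructed` and must not be mistaken for published rules.

Source data spells some predicates inconsistently (`isSimiliarTo` in one
rule listing, `hasGenes` in the ontology table); the canonical forms are
`isSimilarTo`/`hasGene` and the parser accepts the variants as read-time
aliases. Similarly, the printed statement blocks write the gene–disease
association in both directions; we store it gene → disease everywhere, the
direction the ontology declares and the rules match — stored the other way,
the printed inference could not fire at all. The worked-example fixture also
uses one identifier per compound node (`ctdcid9681`) where the printed
blocks mix `ctdcid9681`/`cid9681` for the same entity.

### Fixpoint evaluation

The reference algorithm is naive fixpoint iteration: re-evaluate every rule
against the current graph, record unseen firings, add their heads, repeat
until nothing changes. For the default rule base this converges in two
passes, since `mightHasDisease` feeds no rule body. The engine still guards
user-supplied rule sets with an iteration cap (default 100) and a
diagnostic, because the rule DSL permits recursive heads (e.g. transitive
closure rules), which terminate — heads can only mention body-bound nodes,
so the universe is finite — but may legitimately need many passes.
Materialization is confluent: rule order and body-pattern order do not
affect the resulting graph or path set, which the tests check on randomized
permutations against an independently written backtracking enumerator.

## Term matching

The dictionary annotator mimics a SQL `position()` lookup: case-insensitive
plain substring search, all matches reported, no longest-match suppression.
That is faithful to the described extraction but aggressive — short gene
symbols embedded in ordinary words ("CAT" in "concatenate") match. A
`word_boundary = TRUE` mode requires matches to sit on word boundaries; both
modes are exercised in the tests. The default stays substring because the
worked example depends on it: gene CYP1A2 must be found inside the assay
description "p450-cyp1a2", where the symbol is hyphen-embedded.

The query builder's `contains` filter is case-sensitive by default (the
worked query relies on the exact token "5-HT"); `ignore_case = TRUE` is
available per filter.

## Serialization

N-Triples and Turtle readers/writers are implemented directly: graphs here
use no blank nodes, no collections and no named graphs, so round-trip
equality is exact set equality, and the writers guarantee deterministic
canonical node keys (prefixed names for IRIs, escaped quoted strings with
optional `^^datatype` for literals). The project namespace is the
implementation constant `http://chem.example.org/wo#` bound to prefix `wo`
(the original system never published its base IRI). Literal escaping covers
backslash, quote, newline, carriage return and tab; round-trip fidelity on
adversarial literals is property-tested. Parse errors report line numbers.

Result documents are validated against the shipped JSON schema
(`inst/extdata/schemas/result.schema.json`) by an in-package structural
validator, `validate_result_json()`.

## The synthetic-data generator

`generate_dataset()` emulates the upstream aggregation service's XML output
plus the side tables, with **planted** compound–disease associations of
chosen evidence multiplicity and channel. Defaults mirror the shape of the
worked example: two diseases, one planted through the literature channel at
multiplicity 2 and one through the bioassay channel at multiplicity 1, in
pools of 20 similar compounds, 8 assays, 15 genes, 6 diseases and 10
articles, similarities drawn uniformly from [0.60, 0.95], and a quarter of
records being decoys — values chosen once as a plausible desk-scale slice
of a similarity search around one query compound. Every plant uses fresh
entities (its own gene, compounds, assays/articles), so expected path counts
are exact, not approximate: a literature plant of multiplicity *m* yields
*m* `r6` paths; a bioassay plant yields *m* `r3` plus *m* `r5` paths (the
unanchored and anchored rules both fire); CTD and target plants yield *m*
`r4`/`r7` paths. The ground-truth ledger records the per-rule counts and the
implied ranking. Decoys are records that complete no rule body: neutral
assay descriptions, articles mentioning no gene or only matrix-orphan genes,
targets without disease associations.

What the generator does *not* emulate: real chemistry (SMILES are
placeholders), real literature text (titles and abstracts are templated
strings containing the planted symbols), term ambiguity (planted identifiers
are constructed not to collide, whereas real gene symbols are notoriously
ambiguous), and any noise in the gene–disease matrix. Passing recovery
tests therefore demonstrate that the pipeline is *internally* lossless and
correctly counted — they say nothing about extraction precision on real
assay descriptions or abstracts, where substring matching will produce
false positives.

Determinism: the generator seeds R's RNG from `config$seed`; identical
configs yield byte-identical artifacts, which the tests assert.

## Degenerate inputs and numerical notes

* Empty documents are valid: a record-free XML yields a graph containing
  only the typed query compound; zero paths yield an empty ranking `[]`.
* Similarities are validated to [0, 1] at parse time but carried as their
  verbatim printed strings ("1.000", "0.774") so exports reproduce them
  exactly; no floating-point formatting is applied anywhere.
* `kg_validate()` flags unknown predicates, domain/range violations, and
  multi-typed nodes; untyped nodes are not flagged (unknown is not wrong).
* Graphs are immutable values — every operation returns a new graph.

## Problem sizes used in the test suite

The property suites run at deliberately modest sizes chosen to exercise the
combinatorics without ballooning the suite: 200 random graphs of up to 300
triples with up to 8 random range-restricted rules for oracle equivalence,
50 seeded generator configurations (1–3 plants, multiplicities 1–4, decoy
fractions up to 0.4) for end-to-end recovery, and 100 random graphs per
serialization round-trip check. The brute-force oracles are quadratic or
worse by construction; these sizes keep them honest comparators rather than
bottlenecks.

## Known limitations

* The large-scale behaviour of the original online system (full result sets
  for real drugs against live databases) is out of scope; only the in-paper
  worked examples and synthetic data are reproduced.
* No statistical weighting of paths: evidence paths are counted, not
  scored for independence or importance.
* The query builder covers conjunctive patterns with literal-contains
  filters only — no disjunction, negation or optional patterns.
* Dictionary matching is not named-entity recognition; on real text the
  substring default over-matches and the word-boundary mode under-matches
  multi-word synonyms.
* The gene-family facet requires a user-supplied gene→family table; none is
  bundled.
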