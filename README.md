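# evipath

Evidence-path inference over chemogenomic knowledge graphs.

## The problem

Early in a discovery project a chemist has a query compound and almost no
recorded biology for it. What *is* known is indirect: compounds structurally
similar to the query (with Tanimoto similarities), the bioassays those
compounds are active in, the genes mentioned in those assays' descriptions,
the articles in which similar compounds co-occur with genes, and curated
compound–disease and gene–disease association tables. Each of these is one
hop in a chain; none alone links the query compound to a disease.

`evipath` aggregates this evidence into an ontology-typed triple graph and
forward-chains a declarative rule base over it. A rule such as

```
[r1: (?QueryCompound wo:isSimilarTo ?CompoundID),
     (?CompoundID wo:isActiveIn ?Bioassay),
     (?Bioassay wo:isAssociatedWith ?Disease)
  -> (?QueryCompound wo:mightHasDisease ?Disease)]
```

derives a new `mightHasDisease` statement whenever its body patterns jointly
match. Every firing is recorded as an **evidence path**: the rule id, the
variable binding, and the grounded body triples (the provenance). Two firings
with different bindings are distinct paths even when they derive the same
head statement — a disease supported through two different similar compounds
has genuinely more evidence than one supported through one. Paths are then
clustered by disease and the clusters ranked, by default by the number of
evidence paths, so that the diseases with the most independent support rise
to the top. Facet filters (disease, compound, assay, gene, journal, and
optionally gene family) slice the path set interactively.

The rule base has eight rules covering the four evidence channels (bioassay
activity, literature co-occurrence, curated compound–disease records, and
direct target annotations). Three are kept verbatim from the published rule
listing (`provenance_tag = "paper"`); the other five are reconstructions of
the remaining channels and are tagged as such.

The vocabulary is a small fixed ontology — classes `ChemicalCompound`,
`BioAssay`, `JournalArticle`, `Gene`, `Disease` and typed properties
(`isSimilarTo`, `isActiveIn`, `isContainedIn`, `hasGene`, `hasDisease`,
`isAssociatedWith`, `isrelatedTo`, `hasSimilarity`, `mightHasDisease`, ...)
with domain/range validation. Graphs serialize to N-Triples and Turtle. The
project namespace prefix `wo` is bound to the implementation constant
`http://chem.example.org/wo#`.

## Worked example

The package ships the worked Methysergide example as an exact fixture: two
literature-channel similar compounds (Methysergide itself, similarity
"1.000", and Metergoline, "0.774") co-occurring with gene HTR1B, which the
gene–disease matrix links to Autistic_Disorder, plus one bioassay-channel
compound (similarity "0.929") active in assay aid410 ("p450-cyp1a2"), whose
description yields gene CYP1A2, linked to Lymphoma.

```r
library(evipath)
g <- table3_fixture()
res <- forward_chain(g, default_rules())
res
#> <inference result: 27 input triples, 3 inferred, 4 evidence paths>
ranked <- rank_diseases(res)
as.data.frame(ranked)
#>             disease score     metric rank
#> 1 Autistic_Disorder     2 path_count    1
#> 2          Lymphoma     2 path_count    2
```

The autism association is supported by two evidence paths through two
distinct similar compounds and ranks first (ties break lexicographically).
The lymphoma association is derived twice — once by the verbatim unanchored
bioassay rule for the similar compound itself and once by its query-anchored
variant — and `to_result_json(ranked)` exports the ranking with each path's
rule, supporting compound, verbatim similarity string, intermediate gene or
assay, and publication provenance.

The same flow runs from files — WENDI-style XML plus plain TSV side tables
(gene/disease/GO lexicons, GO annotation, gene–disease matrix):

```r
dir <- system.file("extdata", "methysergide", package = "evipath")
run_pipeline(list(xml = file.path(dir, "wendi.xml"),
                  genes = file.path(dir, "genes.tsv"),
                  diseases = file.path(dir, "diseases.tsv"),
                  matrix = file.path(dir, "gene_disease.tsv"),
                  out_dir = "out"))
```

which writes `out/graph.nt`, `out/paths.json` and `out/ranked.json`. A thin
command-line wrapper with subcommands `generate`, `ingest`, `infer`, `rank`,
`filter`, `query` and `run` is installed at
`system.file("cli", "evipath.R", package = "evipath")`.

Synthetic datasets with known ground truth come from the generator:

```r
ds <- generate_dataset(generator_config(seed = 7))
ds$ground_truth$totals   # planted evidence-path counts per disease
```

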