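Package: evipath
Title: Evidence-Path Inference over Chemogenomic Knowledge Graphs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an ontology-typed RDF-style triple graph from aggregated
    chemogenomic evidence about a query compound (similar compounds with
    Tanimoto similarities, bioassay activities, literature co-occurrences and
    curated compound-disease records), infers new compound-disease
    associations by forward-chaining a declarative triple-pattern rule base,
    records every rule firing as an evidence path with full provenance, and
    clusters, ranks and facet-filters the paths by disease. Includes
    N-Triples and Turtle serialization, dictionary-based gene/disease/GO term
    extraction, a stepwise conjunctive query builder, and a synthetic-data
    generator with planted associations of known evidence multiplicity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
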