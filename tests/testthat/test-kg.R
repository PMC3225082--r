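test_that("adding triples has set semantics", {
  g <- kg_new()
  t1 <- triple("wo:querycmpd", "wo:isSimilarTo", "wo:cid24871487")
  g <- kg_add(g, t1)
  g <- kg_add(g, t1)
  expect_equal(kg_size(g), 1L)
  expect_true(kg_contains(g, t1))

  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:60, 1L)
    nodes <- paste0("wo:m", 1:20)
    ts <- lapply(seq_len(n), function(i) {
      triple(sample(nodes, 1L), sample(RANDOM_PREDICATES, 1L), sample(nodes, 1L))
    })
    keys <- vapply(ts, function(t) paste(t$s$value, t$p$value, t$o$value), character(1))
    g <- kg_add_triples(kg_new(), ts)
    expect_equal(kg_size(g), length(unique(keys)))
  }
})

test_that("malformed terms are rejected by name", {
  expect_error(iri(""), "non-empty")
  expect_error(kg_add(kg_new(), triple(iri("x", prefix = "zz"), "wo:p", "wo:y")),
               "zz:x")
  expect_error(triple(literal("a"), "wo:p", "wo:y"), "subject must be an IRI")
})

test_that("the compound/assay statement blocks type their entities", {
  g <- kg_add_triples(kg_new(), list(
    triple("wo:querycmpd", "wo:isSimilarTo", "wo:cid24871487"),
    triple("wo:cid24871487", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:cid24871487", "wo:isActiveIn", "wo:aid1469"),
    triple("wo:aid1469", "rdf:type", "wo:BioAssay"),
    triple("wo:aid1469", "wo:hasGene", "wo:COL4A4"),
    triple("wo:COL4A4", "rdf:type", "wo:Gene"),
    triple("wo:COL4A4", "wo:isAssociatedWith", "wo:Nephritis"),
    triple("wo:Nephritis", "rdf:type", "wo:Disease")
  ))
  expect_true(kg_contains(g, triple("wo:cid24871487", "rdf:type", "wo:ChemicalCompound")))
  expect_true(kg_contains(g, triple("wo:aid1469", "rdf:type", "wo:BioAssay")))
  ## these blocks conform to the ontology once the query compound is typed
  g <- kg_add(g, triple("wo:querycmpd", "rdf:type", "wo:ChemicalCompound"))
  expect_equal(nrow(kg_validate(g)), 0L)
})

test_that("kg_match enumerates typed compounds in the worked-example graph", {
  hits <- kg_match(table3_fixture(),
                   triple_pattern("?c", "rdf:type", "wo:ChemicalCompound"))
  expect_setequal(hits$c,
                  c("wo:querycmpd", "wo:ctdcid9681", "wo:ctdcid11865408", "wo:cid5486180"))
})

test_that("kg_match equals a naive full scan on random graphs and patterns", {
  set.seed(101)
  for (rep in 1:40) {
    g <- random_graph(sample(10:120, 1L))
    pat <- random_pattern(g)
    got <- bindings_sigs(kg_match(g, pat))
    want <- oracle_match_body(g, list(pat))
    expect_identical(got, want)
  }
  ## all-wildcard pattern on an empty graph
  expect_equal(nrow(kg_match(kg_new(), triple_pattern("?s", "?p", "?o"))), 0L)
  ## repeated variable must bind the same node
  g <- kg_add_triples(kg_new(), list(triple("wo:a", "wo:linksTo", "wo:a"),
                                     triple("wo:a", "wo:linksTo", "wo:b")))
  self <- kg_match(g, triple_pattern("?x", "wo:linksTo", "?x"))
  expect_equal(self$x, "wo:a")
})

test_that("validation flags exactly the violations of a per-triple check", {
  ont <- ce_ontology()
  expect_equal(nrow(kg_validate(table3_fixture(), ont)), 0L)

  ## a gene cannot be the subject of isActiveIn (domain is ChemicalCompound)
  g <- kg_add_triples(kg_new(), list(
    triple("wo:HTR1B", "rdf:type", "wo:Gene"),
    triple("wo:aid410", "rdf:type", "wo:BioAssay"),
    triple("wo:HTR1B", "wo:isActiveIn", "wo:aid410")
  ))
  report <- kg_validate(g, ont)
  expect_equal(nrow(report), 1L)
  expect_match(report$issue, "domain violation")

  ## undeclared predicate, literal/entity range mix-ups, double typing
  g2 <- kg_add_triples(kg_new(), list(
    triple("wo:c1", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:c1", "rdf:type", "wo:Gene"),
    triple("wo:c1", "wo:frobnicates", "wo:c2"),
    triple("wo:c1", "wo:hasSimilarity", "wo:c2"),
    triple("wo:c1", "wo:isSimilarTo", literal("0.9"))
  ))
  report2 <- kg_validate(g2, ont)
  expect_true(any(grepl("more than one rdf:type", report2$issue)))
  expect_true(any(grepl("undeclared predicate", report2$issue)))
  expect_true(any(grepl("expects a literal object", report2$issue)))
  expect_true(any(grepl("expects an entity object", report2$issue)))

  set.seed(202)
  for (rep in 1:10) {
    g3 <- random_graph(sample(10:80, 1L))
    report3 <- kg_validate(g3, ont)
    ## oracle: exhaustive per-triple check
    df <- kg_triples(g3)
    ty <- df[df$p == "rdf:type", , drop = FALSE]
    types <- setNames(sub("^wo:", "", ty$o[!duplicated(ty$s)]), ty$s[!duplicated(ty$s)])
    bad <- 0L
    for (i in seq_len(nrow(df))) {
      s <- df$s[[i]]; p <- sub("^wo:", "", df$p[[i]]); o <- df$o[[i]]
      if (df$p[[i]] == "rdf:type") {
        if (sum(ty$s == s) > 1L) bad <- bad + 1L
        if (!(sub("^wo:", "", o) %in% ont$classes)) bad <- bad + 1L
        next
      }
      decl <- ont$properties[[canonical_predicate(p, ont)]]
      if (is.null(decl)) { bad <- bad + 1L; next }
      if (!is.na(types[s]) && !(types[s] %in% decl$domain)) bad <- bad + 1L
      if (identical(decl$range, "literal")) {
        if (!startsWith(o, "\"")) bad <- bad + 1L
      } else if (startsWith(o, "\"")) {
        bad <- bad + 1L
      } else if (!is.na(types[o]) && !(types[o] %in% decl$range)) {
        bad <- bad + 1L
      }
    }
    expect_equal(nrow(report3), bad)
  }
})

test_that("predicate aliases canonicalize", {
  expect_equal(canonical_predicate("hasGenes"), "hasGene")
  expect_equal(canonical_predicate("isSimiliarTo"), "isSimilarTo")
  expect_equal(canonical_predicate("hasGene"), "hasGene")
})
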