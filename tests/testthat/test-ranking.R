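table3_result <- function() forward_chain(table3_fixture(), default_rules())

test_that("clustering partitions paths by inferred disease", {
  res <- table3_result()
  clusters <- cluster_by_disease(res)
  expect_length(clusters, 2L)
  sizes <- setNames(vapply(clusters, function(cl) length(cl$paths), integer(1)),
                    vapply(clusters, function(cl) cl$disease, character(1)))
  expect_equal(sizes[["wo:Autistic_Disorder"]], 2L)
  expect_equal(sizes[["wo:Lymphoma"]], 2L)  # verbatim r3 plus anchored r5
  expect_equal(sum(sizes), length(res$paths))

  expect_length(cluster_by_disease(forward_chain(kg_new(), list())), 0L)

  ## partition property on random inference results
  set.seed(113)
  for (rep in 1:6) {
    ds <- generate_dataset(random_generator_config(rep + 20L))
    res2 <- run_generated(ds)
    clusters2 <- cluster_by_disease(res2)
    expect_equal(sum(vapply(clusters2, function(cl) length(cl$paths), integer(1))),
                 length(res2$paths))
    for (cl in clusters2) {
      heads <- vapply(cl$paths, function(p) p$inferred$o[[1]], character(1))
      expect_true(all(heads == cl$disease))
    }
  }
})

test_that("path_count ranking orders the worked example correctly", {
  res <- table3_result()
  ranked <- rank_diseases(res)
  expect_equal(ranked$disease, c("Autistic_Disorder", "Lymphoma"))
  expect_equal(ranked$rank, c(1L, 2L))
  expect_equal(ranked$score[[1]], 2)
  expect_true(all(diff(ranked$score) <= 0))
})

test_that("property_count reproduces the literal aggregate query", {
  res <- table3_result()
  clusters <- cluster_by_disease(res)
  ranked <- rank_clusters(clusters, "property_count", graph = res$graph)
  ## naive scan-and-count over the materialized graph
  df <- kg_triples(res$graph)
  for (i in seq_len(nrow(ranked))) {
    expect_equal(ranked$score[[i]], sum(df$s == paste0("wo:", ranked$disease[[i]])))
  }
  ## regression: the shared gene-disease triple makes the metrics disagree --
  ## Lymphoma has two evidence paths but only one subject statement (its typing)
  pc <- rank_clusters(clusters, "path_count")
  expect_equal(pc$score[pc$disease == "Lymphoma"], 2)
  expect_equal(ranked$score[ranked$disease == "Lymphoma"], 1)

  expect_error(rank_clusters(clusters, "bogus_metric"), "metric")
  expect_error(rank_clusters(clusters, "property_count"), "graph")
})

test_that("single cluster ranks first under either metric", {
  g <- kg_add_triples(kg_new(), list(
    triple("wo:querycmpd", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:querycmpd", "wo:isSimilarTo", "wo:cid1"),
    triple("wo:cid1", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:cid1", "wo:hasDisease", "wo:D1"),
    triple("wo:D1", "rdf:type", "wo:Disease")
  ))
  res <- forward_chain(g, default_rules())
  for (m in c("path_count", "property_count")) {
    ranked <- rank_clusters(cluster_by_disease(res), m, graph = res$graph)
    expect_equal(ranked$rank, 1L)
    expect_equal(ranked$disease, "D1")
  }
})

test_that("re-ranking is idempotent and ranks have no gaps", {
  set.seed(114)
  ds <- generate_dataset(random_generator_config(31L))
  res <- run_generated(ds)
  clusters <- cluster_by_disease(res)
  r1 <- rank_clusters(clusters, "path_count")
  r2 <- rank_clusters(attr(r1, "clusters"), "path_count")
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$rank, seq_len(nrow(r1)))
  expect_true(all(diff(r1$score) <= 0))
})

test_that("facet filters select by role and compose by intersection", {
  res <- table3_result()
  by_disease <- facet_filter(res, "disease", "Autistic_Disorder")
  expect_length(by_disease$paths, 2L)
  expect_setequal(vapply(by_disease$paths, function(p) p$binding[["CompoundID"]],
                         character(1)),
                  c("wo:ctdcid9681", "wo:ctdcid11865408"))

  by_assay <- facet_filter(res, "assay", "aid410")
  expect_length(by_assay$paths, 2L)  # the r3 and r5 Lymphoma firings
  expect_true(all(vapply(by_assay$paths, function(p) p$inferred$o[[1]], character(1))
                  == "wo:Lymphoma"))

  ## absent values and class mismatches yield the empty set
  expect_length(facet_filter(res, "disease", "Nephritis")$paths, 0L)
  expect_length(facet_filter(res, "gene", "aid410")$paths, 0L)

  ## subset, idempotence, commutativity
  f1 <- facet_filter(res, "compound", "ctdcid9681")
  expect_true(all(vapply(f1$paths, function(p) p$rule_id, character(1)) %in%
                  vapply(res$paths, function(p) p$rule_id, character(1))))
  expect_length(facet_filter(f1, "compound", "ctdcid9681")$paths, length(f1$paths))
  ab <- facet_filter(facet_filter(res, "disease", "Autistic_Disorder"),
                     "gene", "HTR1B")
  ba <- facet_filter(facet_filter(res, "gene", "HTR1B"),
                     "disease", "Autistic_Disorder")
  expect_equal(length(ab$paths), length(ba$paths))
  expect_length(ab$paths, 2L)

  ## journal facet: by node id and by title literal (resolved via the graph)
  g <- kg_add_triples(kg_new(), list(
    triple("wo:cid1", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:cid1", "wo:isContainedIn", "wo:pubmedid1"),
    triple("wo:pubmedid1", "rdf:type", "wo:JournalArticle"),
    triple("wo:pubmedid1", "wo:hasTitle", literal("A 5-HT1B binding study")),
    triple("wo:pubmedid1", "wo:hasGene", "wo:GENE1"),
    triple("wo:GENE1", "rdf:type", "wo:Gene"),
    triple("wo:GENE1", "wo:isAssociatedWith", "wo:Dis1"),
    triple("wo:Dis1", "rdf:type", "wo:Disease")
  ))
  res2 <- forward_chain(g, default_rules())
  expect_length(facet_filter(res2, "journal", "pubmedid1")$paths, 1L)
  expect_length(facet_filter(res2, "journal", "wo:pubmedid1")$paths, 1L)
  expect_length(
    facet_filter(res2, "journal", "\"A 5-HT1B binding study\"")$paths, 1L)
})

test_that("gene_family facet needs and uses a family table", {
  res <- table3_result()
  expect_error(facet_filter(res, "gene_family", "serotonin receptors"), "family")
  fams <- data.frame(gene = c("HTR1B", "HTR2A"),
                     family = c("serotonin receptors", "serotonin receptors"),
                     stringsAsFactors = FALSE)
  hit <- facet_filter(res, "gene_family", "serotonin receptors", families = fams)
  expect_length(hit$paths, 2L)
  miss <- facet_filter(res, "gene_family", "kinases", families = fams)
  expect_length(miss$paths, 0L)
})

test_that("result JSON is schema-valid with ordered, stable fields", {
  res <- table3_result()
  ranked <- rank_diseases(res)
  txt <- to_result_json(ranked)
  expect_length(validate_result_json(txt), 0L)
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_equal(doc[[1]]$disease, "Autistic_Disorder")
  expect_length(doc[[1]]$paths, 2L)
  expect_equal(names(doc[[1]]), c("disease", "score", "paths"))
  expect_equal(names(doc[[1]]$paths[[1]])[1:2], c("rule", "similar_compound"))
  ## the Lymphoma evidence carries its verbatim similarity literal
  lym <- doc[vapply(doc, `[[`, character(1), "disease") == "Lymphoma"][[1]]
  expect_equal(unique(vapply(lym$paths, `[[`, character(1), "similarity")), "0.929")

  ## empty ranking: empty array
  empty <- rank_clusters(list(), "path_count")
  expect_equal(as.character(to_result_json(empty)), "[]")

  ## malformed documents are reported
  expect_gt(length(validate_result_json("[{\"disease\": 3}]")), 0L)
  expect_gt(length(validate_result_json("{\"not\": \"an array\"}")), 0L)
})
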