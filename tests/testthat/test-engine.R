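test_that("match_body on the worked-example graph finds the literature bindings", {
  g <- table3_fixture()
  rules <- default_rules()
  ## verbatim Rule 1/2 find nothing here (no assay-disease edges, no journals)
  expect_equal(nrow(match_body(g, rules[[1]]$body)), 0L)
  expect_equal(nrow(match_body(g, rules[[2]]$body)), 0L)
  ## the anchored literature rule yields the two printed bindings via HTR1B
  b6 <- match_body(g, rules[[6]]$body)
  expect_equal(nrow(b6), 2L)
  expect_setequal(b6$CompoundID, c("wo:ctdcid9681", "wo:ctdcid11865408"))
  expect_equal(unique(b6$Gene), "wo:HTR1B")
  expect_equal(unique(b6$Disease), "wo:Autistic_Disorder")
  ## empty graph
  expect_equal(nrow(match_body(kg_new(), rules[[1]]$body)), 0L)
})

test_that("match_body result is independent of body pattern order", {
  set.seed(404)
  for (rep in 1:20) {
    g <- random_graph(sample(20:120, 1L))
    r <- random_safe_rule("x")
    want <- bindings_sigs(match_body(g, r$body))
    perm <- sample(r$body)
    expect_identical(bindings_sigs(match_body(g, perm)), want)
  }
})

test_that("match_body equals brute-force enumeration on random graphs", {
  set.seed(505)
  for (rep in 1:40) {
    g <- random_graph(sample(10:150, 1L))
    r <- random_safe_rule("x")
    expect_identical(bindings_sigs(match_body(g, r$body)),
                     oracle_match_body(g, r$body))
  }
})

test_that("forward chaining on the worked example infers both diseases", {
  res <- forward_chain(table3_fixture(), default_rules())
  inferred <- paste(res$inferred$s, res$inferred$p, res$inferred$o)
  expect_true("wo:querycmpd wo:mightHasDisease wo:Autistic_Disorder" %in% inferred)
  expect_true("wo:querycmpd wo:mightHasDisease wo:Lymphoma" %in% inferred)
  ## verbatim Rule 3 also fires on the unanchored similar compound
  expect_true("wo:cid5486180 wo:mightHasDisease wo:Lymphoma" %in% inferred)
  expect_length(res$paths, 4L)
  ## two literature paths with distinct compounds infer the same head triple
  r6 <- Filter(function(p) p$rule_id == "r6", res$paths)
  expect_length(r6, 2L)
  expect_equal(length(unique(vapply(r6, function(p) p$binding[["CompoundID"]],
                                    character(1)))), 2L)
})

test_that("no rules means no change and no paths", {
  g <- table3_fixture()
  res <- forward_chain(g, list())
  expect_true(kg_equal(res$graph, g))
  expect_length(res$paths, 0L)
})

test_that("forward chaining equals the naive fixpoint oracle on random inputs", {
  set.seed(606)
  for (rep in 1:25) {
    g <- random_graph(sample(15:120, 1L))
    rules <- lapply(seq_len(sample(1:5, 1L)), function(i) {
      random_safe_rule(paste0("g", i))
    })
    res <- forward_chain(g, rules)
    want <- oracle_forward_chain(g, rules)
    expect_identical(result_triples(res), want$triples)
    expect_identical(result_path_ids(res), want$path_ids)
  }
})

test_that("materialization is confluent under rule and pattern permutations", {
  set.seed(707)
  for (rep in 1:10) {
    g <- random_graph(sample(20:100, 1L))
    rules <- lapply(1:4, function(i) random_safe_rule(paste0("g", i)))
    ref <- forward_chain(g, rules)
    shuffled <- lapply(sample(rules), function(r) {
      rule(r$id, sample(r$body), r$head, r$provenance_tag)
    })
    res <- forward_chain(g, shuffled)
    expect_identical(result_triples(res), result_triples(ref))
    expect_identical(result_path_ids(res), result_path_ids(ref))
  }
})

test_that("inference is idempotent and monotone", {
  set.seed(808)
  for (rep in 1:8) {
    g <- random_graph(sample(20:80, 1L))
    rules <- lapply(1:3, function(i) random_safe_rule(paste0("g", i)))
    res <- forward_chain(g, rules)
    again <- forward_chain(res$graph, rules)
    expect_equal(nrow(again$inferred), 0L)
    expect_identical(result_path_ids(again), result_path_ids(res))

    ## monotonicity: adding input triples never removes inferences
    extra <- random_graph(10)
    g2 <- kg_add_triples(g, apply(kg_triples(extra), 1L, function(r) {
      triple(r[["s"]], r[["p"]], r[["o"]])
    }))
    res2 <- forward_chain(g2, rules)
    expect_true(all(result_triples(res) %in% result_triples(res2)))
    expect_true(all(result_path_ids(res) %in% result_path_ids(res2)))
  }
})

test_that("evidence paths are sound: grounded bodies sit in the graph", {
  set.seed(909)
  g <- random_graph(100)
  rules <- lapply(1:4, function(i) random_safe_rule(paste0("g", i)))
  res <- forward_chain(g, rules)
  all_keys <- result_triples(res)
  for (p in res$paths) {
    r <- rules[[match(p$rule_id, vapply(rules, function(x) x$id, character(1)))]]
    ## substituting the binding into the rule body reproduces the grounded body
    expected <- vapply(r$body, function(pat) {
      slot <- function(x) if (startsWith(x, "?")) p$binding[[substring(x, 2L)]] else x
      paste(slot(pat$s), slot(pat$p), slot(pat$o))
    }, character(1))
    got <- paste(p$grounded_body$s, p$grounded_body$p, p$grounded_body$o)
    expect_identical(got, expected)
    expect_true(all(got %in% all_keys))
  }
})

test_that("recursive rule sets hit the iteration cap with a diagnostic", {
  ## grows a chain one node long per iteration via a self-feeding head; the
  ## node vocabulary is finite so it terminates, but a tiny cap must trip
  g <- kg_add_triples(kg_new(), list(
    triple("wo:n1", "wo:linksTo", "wo:n2"),
    triple("wo:n2", "wo:linksTo", "wo:n3"),
    triple("wo:n3", "wo:linksTo", "wo:n4")
  ))
  transitive <- rule("t", list(triple_pattern("?a", "wo:linksTo", "?b"),
                               triple_pattern("?b", "wo:linksTo", "?c")),
                     list(triple_pattern("?a", "wo:linksTo", "?c")))
  expect_error(forward_chain(g, list(transitive), max_iterations = 1L), "fixpoint")
  res <- forward_chain(g, list(transitive))
  expect_equal(kg_size(res$graph), 6L)  # transitive closure of a 4-chain
})

test_that("verbatim Rule 2 fires on journal-mediated literature graphs", {
  g <- kg_add_triples(kg_new(), list(
    triple("wo:cid1", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:cid1", "wo:isContainedIn", "wo:pubmedid1"),
    triple("wo:pubmedid1", "rdf:type", "wo:JournalArticle"),
    triple("wo:pubmedid1", "wo:hasGene", "wo:GENE1"),
    triple("wo:GENE1", "rdf:type", "wo:Gene"),
    triple("wo:GENE1", "wo:isAssociatedWith", "wo:Dis1"),
    triple("wo:Dis1", "rdf:type", "wo:Disease")
  ))
  res <- forward_chain(g, default_rules())
  expect_identical(vapply(res$paths, function(p) p$rule_id, character(1)), "r2")
  expect_true(kg_contains(res$graph, triple("wo:cid1", "wo:mightHasDisease", "wo:Dis1")))
})
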