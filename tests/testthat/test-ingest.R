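test_that("the shipped worked-example document parses into its groups", {
  inp <- methysergide_inputs()
  rec <- parse_wendi_xml(inp$xml)
  expect_equal(rec$query_compound$id, "querycmpd")
  expect_length(rec$groups$Literature, 2L)
  expect_length(rec$groups$ActiveBioassay, 1L)
  expect_length(rec$groups$CTD, 0L)
  lit <- rec$groups$Literature
  expect_setequal(vapply(lit, `[[`, character(1), "similar_compound"),
                  c("ctdcid9681", "ctdcid11865408"))
  expect_setequal(vapply(lit, `[[`, character(1), "similarity_chr"),
                  c("1.000", "0.774"))
  ba <- rec$groups$ActiveBioassay[[1]]
  expect_equal(ba$similar_compound, "cid5486180")
  expect_equal(ba$similarity, 0.929)
  expect_equal(ba$payload$aid, "aid410")
})

test_that("documents with no records keep the query compound", {
  doc <- "<wendi query=\"querycmpd\"/>"
  rec <- parse_wendi_xml(doc)
  expect_equal(rec$query_compound$id, "querycmpd")
  expect_equal(sum(vapply(rec$groups, length, integer(1))), 0L)
  g <- wendi_to_triples(rec,
                        lexicon(character(0), character(0), "gene"),
                        lexicon(character(0), character(0), "disease"),
                        lexicon(character(0), character(0), "go_term"),
                        data.frame(go_id = character(0), gene = character(0)),
                        data.frame(gene = character(0), disease = character(0),
                                   provenance = character(0)))
  expect_equal(kg_size(g), 1L)
  expect_true(kg_contains(g, triple("wo:querycmpd", "rdf:type", "wo:ChemicalCompound")))
})

test_that("schema violations are rejected with a message", {
  expect_error(parse_wendi_xml("<wendi query=\"q\"><group name=\"Bogus\"/></wendi>"),
               "schema")
  expect_error(parse_wendi_xml(
    "<wendi query=\"q\"><group name=\"CTD\"><record cid=\"c\" similarity=\"1.2\"><disease id=\"D\"/></record></group></wendi>"),
    "schema")
})

test_that("term extraction matches the naive substring scan", {
  genes <- lexicon(c("CYP1A2", "HTR1B", "CAT"), c("CYP1A2", "HTR1B", "CAT"), "gene")
  hits <- extract_terms("p450-cyp1a2", genes)
  expect_equal(hits$id, "CYP1A2")
  expect_equal(hits$offset, 6L)

  ## substring mode reports embedded symbols; word-boundary mode does not
  expect_equal(extract_terms("concatenate the results", genes)$id, "CAT")
  expect_equal(nrow(extract_terms("concatenate the results", genes,
                                  word_boundary = TRUE)), 0L)
  expect_equal(extract_terms("the cat gene", genes, word_boundary = TRUE)$id, "CAT")
  expect_equal(nrow(extract_terms("", genes)), 0L)

  ## randomized: equals a naive O(text * lexicon) scan in both modes
  set.seed(110)
  vocab <- c("ABC1", "XYZ9", "LONGGENE2", "GG7")
  lex <- lexicon(vocab, vocab, "gene")
  words <- c("filler", "tokens", "without", "matches", vocab, tolower(vocab))
  for (rep in 1:25) {
    text <- paste(sample(words, sample(3:12, 1L), replace = TRUE), collapse = " ")
    for (wb in c(FALSE, TRUE)) {
      got <- extract_terms(text, lex, word_boundary = wb)
      naive <- character(0)
      for (v in vocab) {
        found <- if (wb) {
          grepl(paste0("\\b", v, "\\b"), text, ignore.case = TRUE, perl = TRUE)
        } else {
          grepl(tolower(v), tolower(text), fixed = TRUE)
        }
        if (found) naive <- c(naive, v)
      }
      expect_setequal(got$id, naive)
      expect_false(is.unsorted(got$offset))
    }
  }
})

test_that("GO expansion and gene-disease lookup are set operations", {
  ann <- data.frame(go_id = c("GO:1", "GO:1", "GO:2", "GO:3"),
                    gene = c("A", "B", "B", "C"), stringsAsFactors = FALSE)
  expect_equal(go_terms_to_genes(character(0), ann), character(0))
  expect_equal(go_terms_to_genes(c("GO:1", "GO:2"), ann), c("A", "B"))
  expect_equal(go_terms_to_genes("GO:nope", ann), character(0))

  m <- data.frame(gene = c("HTR1B", "CYP1A2", "HTR1B"),
                  disease = c("Autistic_Disorder", "Lymphoma", "Migraine_Disorder"),
                  provenance = c("pubmedid19038234", "", "pubmedid1"),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(genes_to_diseases(character(0), m)), 0L)
  hit <- genes_to_diseases("HTR1B", m)
  expect_equal(nrow(hit), 2L)
  expect_true(all(hit$gene == "HTR1B"))

  set.seed(111)
  for (rep in 1:10) {
    genes <- sample(LETTERS, sample(1:6, 1L))
    big <- data.frame(gene = sample(LETTERS, 40, replace = TRUE),
                      disease = sample(paste0("D", 1:8), 40, replace = TRUE),
                      provenance = "", stringsAsFactors = FALSE)
    expect_identical(genes_to_diseases(genes, big), {
      out <- big[big$gene %in% genes, , drop = FALSE]; rownames(out) <- NULL; out
    })
  }
})

test_that("triple emission reproduces the printed statement blocks", {
  g <- methysergide_graph()
  t3 <- table3_fixture()
  keys <- function(x) paste(kg_triples(x)$s, kg_triples(x)$p, kg_triples(x)$o)
  ## every printed triple is emitted
  expect_true(all(keys(t3) %in% keys(g)))
  ## and the only additions are the journal bookkeeping triples
  extra <- setdiff(keys(g), keys(t3))
  expect_length(extra, 6L)
  expect_true(all(grepl("isContainedIn|hasTitle|JournalArticle", extra)))
  expect_equal(nrow(kg_validate(g)), 0L)
})

test_that("emitted graphs always validate and keep records reachable", {
  set.seed(112)
  for (seed in 1:6) {
    ds <- generate_dataset(random_generator_config(seed))
    tmp <- tempfile(fileext = ".xml")
    writeLines(ds$xml, tmp, sep = "")
    rec <- parse_wendi_xml(tmp)
    g <- wendi_to_triples(rec, ds$gene_lexicon, ds$disease_lexicon,
                          ds$go_lexicon, ds$go_annotation, ds$gene_disease)
    expect_equal(nrow(kg_validate(g)), 0L)
    ## no information loss: every record's compound hangs off the query node
    df <- kg_triples(g)
    sims <- df$o[df$s == "wo:querycmpd" & df$p == "wo:isSimilarTo"]
    for (group in names(rec$groups)) {
      for (r in rec$groups[[group]]) {
        expect_true(paste0("wo:", r$similar_compound) %in% sims)
      }
    }
    unlink(tmp)
  }
})
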