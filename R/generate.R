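## Synthetic WENDI-style datasets with planted compound-disease associations
## of known evidence-path multiplicity, plus exact fixtures for the worked
## examples used throughout the tests.

CHANNELS <- c("bioassay", "literature", "ctd", "chembl")

## evidence paths each channel record produces under the default rule base
CHANNEL_RULES <- list(
  bioassay   = c("r3", "r5"),  # verbatim Rule 3 fires on the similar compound,
                               # r5 on the query compound: two paths per record
  literature = "r6",
  ctd        = "r4",
  chembl     = "r7"
)

#' Configure the synthetic-data generator
#'
#' @param n_similar_compounds,n_bioassays,n_genes,n_diseases,n_articles Pool
#'   sizes; must be large enough to host the planted records and decoys.
#' @param planted List of plants, each `list(disease = <id or NULL>, channels
#'   = list(list(channel = <one of bioassay/literature/ctd/chembl>,
#'   multiplicity = m)))`. `NULL` diseases are auto-named. The default plants
#'   two diseases with literature multiplicity 2 and bioassay multiplicity 1,
#'   the shape of the worked Methysergide example.
#' @param similarity_range Tanimoto similarities are drawn uniformly from this
#'   subinterval of (0, 1].
#' @param decoy_fraction Fraction of all records that are decoys: records
#'   completing no rule body (neutral assay descriptions, articles mentioning
#'   no or only matrix-orphan genes, targets with no disease association).
#' @param go_fraction Fraction of bioassay plant records realized through a
#'   GO-term mention (expanded via the GO annotation) instead of a direct
#'   gene-symbol mention.
#' @param seed RNG seed; identical configs and seeds yield byte-identical
#'   artifacts.
#' @return A `generator_config`.
#' @export
generator_config <- function(n_similar_compounds = 20L, n_bioassays = 8L,
                             n_genes = 15L, n_diseases = 6L, n_articles = 10L,
                             planted = list(
                               list(disease = NULL,
                                    channels = list(list(channel = "literature", multiplicity = 2L))),
                               list(disease = NULL,
                                    channels = list(list(channel = "bioassay", multiplicity = 1L)))
                             ),
                             similarity_range = c(0.6, 0.95),
                             decoy_fraction = 0.25, go_fraction = 0,
                             seed = 42L) {
  cfg <- structure(list(
    n_similar_compounds = as.integer(n_similar_compounds),
    n_bioassays = as.integer(n_bioassays), n_genes = as.integer(n_genes),
    n_diseases = as.integer(n_diseases), n_articles = as.integer(n_articles),
    planted = planted, similarity_range = similarity_range,
    decoy_fraction = decoy_fraction, go_fraction = go_fraction,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (plant in cfg$planted) {
    for (ch in plant$channels) {
      if (!(ch$channel %in% CHANNELS)) {
        stop("unknown evidence channel '", ch$channel, "'; expected one of ",
             paste(CHANNELS, collapse = ", "), call. = FALSE)
      }
      if (ch$multiplicity < 1L) stop("planted multiplicities must be >= 1", call. = FALSE)
    }
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 1) {
    stop("decoy_fraction must lie in [0, 1)", call. = FALSE)
  }
  lo <- cfg$similarity_range[[1]]; hi <- cfg$similarity_range[[2]]
  if (lo <= 0 || hi > 1 || lo > hi) {
    stop("similarity_range must be a subinterval of (0, 1]", call. = FALSE)
  }
  counts <- plan_counts(cfg)
  shortfalls <- c(
    if (counts$compounds > cfg$n_similar_compounds)
      paste0("n_similar_compounds (", cfg$n_similar_compounds, ") < records needed (",
             counts$compounds, ")"),
    if (counts$assays > cfg$n_bioassays)
      paste0("n_bioassays (", cfg$n_bioassays, ") < bioassay records (", counts$assays, ")"),
    if (counts$articles > cfg$n_articles)
      paste0("n_articles (", cfg$n_articles, ") < literature records (", counts$articles, ")"),
    if (counts$genes > cfg$n_genes)
      paste0("n_genes (", cfg$n_genes, ") < genes needed (", counts$genes, ")"),
    if (counts$diseases > cfg$n_diseases)
      paste0("n_diseases (", cfg$n_diseases, ") < planted diseases (", counts$diseases, ")")
  )
  if (length(shortfalls) > 0L) {
    stop("infeasible generator config: ", paste(shortfalls, collapse = "; "), call. = FALSE)
  }
  invisible(cfg)
}

plan_counts <- function(cfg) {
  n_plant <- 0L; n_assay <- 0L; n_article <- 0L; n_gene <- 0L
  for (plant in cfg$planted) {
    for (ch in plant$channels) {
      m <- as.integer(ch$multiplicity)
      n_plant <- n_plant + m
      if (ch$channel == "bioassay") n_assay <- n_assay + m
      if (ch$channel == "literature") n_article <- n_article + m
      if (ch$channel %in% c("bioassay", "literature", "chembl")) n_gene <- n_gene + 1L
    }
  }
  n_decoy <- if (cfg$decoy_fraction > 0) {
    max(1L, round(cfg$decoy_fraction * n_plant / (1 - cfg$decoy_fraction)))
  } else 0L
  ## decoys cycle bioassay / literature / chembl; worst case per kind:
  decoy_assays <- ceiling(n_decoy / 3)
  decoy_articles <- ceiling(2 * n_decoy / 3)
  decoy_genes <- ceiling(2 * n_decoy / 3)
  list(compounds = n_plant + n_decoy,
       assays = n_assay + decoy_assays,
       articles = n_article + decoy_articles,
       genes = n_gene + decoy_genes,
       diseases = length(cfg$planted),
       n_plant = n_plant, n_decoy = n_decoy)
}

## deterministic pseudo-biological identifier pools
make_gene_symbols <- function(n) {
  pool <- apply(expand.grid(LETTERS[seq(2, 26, 2)], LETTERS[seq(1, 25, 2)],
                            c("R", "K", "M", "T"), 1:9), 1L, paste, collapse = "")
  sample(pool, n)
}

make_disease_names <- function(n) {
  stems <- c("Cardi", "Neur", "Hepat", "Nephr", "Oste", "Arthr", "Pulmon",
             "Gastr", "Myel", "Derm", "Angi", "Encephal")
  tails <- c("osis", "itis", "opathy", "algia")
  kinds <- c("Disorder", "Syndrome", "Disease")
  pool <- apply(expand.grid(stems, tails, kinds), 1L,
                function(r) paste0(r[[1]], r[[2]], "_", r[[3]]))
  sample(pool, n)
}

fmt_sim <- function(x) sprintf("%.3f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Generate a synthetic WENDI-style dataset with known ground truth
#'
#' @param config A `generator_config`.
#' @return A `synthetic_dataset`: list with `xml` (the WENDI document text),
#'   the side tables (`gene_lexicon`, `disease_lexicon`, `go_lexicon`,
#'   `go_annotation`, `gene_disease` data frames) and `ground_truth` (per
#'   planted disease: the expected evidence-path count per rule and in total,
#'   the expected ranking order, and per-group record counts).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_config(config)
  set.seed(config$seed)
  counts <- plan_counts(config)

  gene_pool <- make_gene_symbols(config$n_genes)
  disease_pool <- make_disease_names(config$n_diseases)
  cid_pool <- paste0("cid", 100000L + sample.int(9899999L, config$n_similar_compounds))
  aid_pool <- paste0("aid", 100L + sample.int(99899L, config$n_bioassays))
  n_pmid <- config$n_articles + counts$n_plant + counts$n_decoy +
    4L * length(config$planted)
  pmid_pool <- paste0("pubmedid", 1000000L + sample.int(8999999L, n_pmid))
  next_gene <- 0L; next_cid <- 0L; next_aid <- 0L; next_pmid <- 0L; next_dis <- 0L
  take <- function(pool, i) { if (i > length(pool)) stop("pool exhausted", call. = FALSE); pool[[i]] }

  records <- list()  # each: list(group=, cid=, sim=, ...payload fields)
  matrix_rows <- list()
  go_rows <- list()
  go_lex_rows <- list()
  truth_rows <- list()

  go_counter <- 0L
  planted_diseases <- character(0)

  for (plant in config$planted) {
    if (is.null(plant$disease)) {
      next_dis <- next_dis + 1L
      disease <- take(disease_pool, next_dis)
    } else {
      disease <- plant$disease
    }
    planted_diseases <- c(planted_diseases, disease)
    for (ch in plant$channels) {
      m <- as.integer(ch$multiplicity)
      gene <- NULL
      if (ch$channel %in% c("bioassay", "literature", "chembl")) {
        next_gene <- next_gene + 1L
        gene <- take(gene_pool, next_gene)
        next_pmid <- next_pmid + 1L
        assoc_pmid <- take(pmid_pool, next_pmid)
        matrix_rows[[length(matrix_rows) + 1L]] <-
          c(gene = gene, disease = disease, provenance = assoc_pmid)
      }
      go_id <- NULL
      if (ch$channel == "bioassay" && config$go_fraction > 0) {
        go_counter <- go_counter + 1L
        go_id <- sprintf("GO:%07d", 6900 + go_counter)
        go_surface <- paste0("kinase cascade regulation module ", go_counter)
        go_lex_rows[[length(go_lex_rows) + 1L]] <- c(term = go_surface, id = go_id)
        go_rows[[length(go_rows) + 1L]] <- c(go_id = go_id, gene = gene)
      }
      sims <- fmt_sim(stats::runif(m, config$similarity_range[[1]],
                                   config$similarity_range[[2]]))
      via_go_flags <- if (ch$channel == "bioassay" && config$go_fraction > 0) {
        stats::runif(m) < config$go_fraction
      } else rep(FALSE, m)
      for (i in seq_len(m)) {
        next_cid <- next_cid + 1L
        cid <- take(cid_pool, next_cid)
        rec <- switch(ch$channel,
          bioassay = {
            next_aid <- next_aid + 1L
            aid <- take(aid_pool, next_aid)
            desc <- if (via_go_flags[[i]]) {
              paste0("High-throughput screen of ",
                     paste0("kinase cascade regulation module ", go_counter),
                     " modulators")
            } else {
              paste0("Dose-response inhibition assay targeting ", gene)
            }
            list(group = "ActiveBioassay", cid = cid, sim = sims[[i]],
                 aid = aid, description = desc)
          },
          literature = {
            next_pmid <- next_pmid + 1L
            pmid <- take(pmid_pool, next_pmid)
            list(group = "Literature", cid = paste0("ctd", cid), sim = sims[[i]],
                 article = pmid,
                 title = paste0("Modulation of ", gene, " signalling by compound ", cid),
                 abstract = paste0("Treatment with compound ", cid,
                                   " altered expression of ", gene, " in vitro."))
          },
          ctd = {
            next_pmid <- next_pmid + 1L
            list(group = "CTD", cid = paste0("ctd", cid), sim = sims[[i]],
                 disease = disease, provenance = take(pmid_pool, next_pmid))
          },
          chembl = {
            list(group = "Chembl", cid = cid, sim = sims[[i]], gene = gene)
          }
        )
        records[[length(records) + 1L]] <- rec
      }
      for (rid in CHANNEL_RULES[[ch$channel]]) {
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(disease = disease, channel = ch$channel, rule = rid,
                     n_paths = m, stringsAsFactors = FALSE)
      }
    }
  }

  ## decoys: records that complete no rule body
  decoy_genes <- character(0)
  for (k in seq_len(counts$n_decoy)) {
    next_cid <- next_cid + 1L
    cid <- take(cid_pool, next_cid)
    sim <- fmt_sim(stats::runif(1, config$similarity_range[[1]],
                                config$similarity_range[[2]]))
    kind <- k %% 3L
    rec <- if (kind == 0L) {
      next_aid <- next_aid + 1L
      list(group = "ActiveBioassay", cid = cid, sim = sim,
           aid = take(aid_pool, next_aid),
           description = paste0("Colorimetric viability counterscreen panel ", k))
    } else if (kind == 1L) {
      next_pmid <- next_pmid + 1L
      next_gene <- next_gene + 1L
      orphan <- take(gene_pool, next_gene)  # in the lexicon, absent from the matrix
      decoy_genes <- c(decoy_genes, orphan)
      list(group = "Literature", cid = paste0("ctd", cid), sim = sim,
           article = take(pmid_pool, next_pmid),
           title = paste0("A structural survey of compound ", cid),
           abstract = paste0("Binding of compound ", cid, " to ", orphan,
                             " was not reproducible."))
    } else {
      next_gene <- next_gene + 1L
      orphan <- take(gene_pool, next_gene)
      decoy_genes <- c(decoy_genes, orphan)
      list(group = "Chembl", cid = cid, sim = sim, gene = orphan)
    }
    records[[length(records) + 1L]] <- rec
  }

  used_genes <- gene_pool[seq_len(next_gene)]
  gene_lex <- lexicon(used_genes, used_genes, "gene")
  all_dis <- unique(c(planted_diseases, disease_pool))
  disease_lex <- lexicon(tolower(gsub("_", " ", all_dis)), all_dis, "disease")
  go_lex <- if (length(go_lex_rows) > 0L) {
    m <- do.call(rbind, go_lex_rows)
    lexicon(m[, "term"], m[, "id"], "go_term")
  } else lexicon(character(0), character(0), "go_term")
  go_ann <- if (length(go_rows) > 0L) {
    m <- do.call(rbind, go_rows)
    data.frame(go_id = m[, "go_id"], gene = m[, "gene"], stringsAsFactors = FALSE)
  } else data.frame(go_id = character(0), gene = character(0), stringsAsFactors = FALSE)
  gd <- if (length(matrix_rows) > 0L) {
    m <- do.call(rbind, matrix_rows)
    data.frame(gene = m[, "gene"], disease = m[, "disease"],
               provenance = m[, "provenance"], stringsAsFactors = FALSE)
  } else data.frame(gene = character(0), disease = character(0),
                    provenance = character(0), stringsAsFactors = FALSE)

  per_rule <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame(disease = character(0), channel = character(0), rule = character(0),
               n_paths = integer(0), stringsAsFactors = FALSE)
  totals <- if (nrow(per_rule) > 0L) {
    agg <- stats::aggregate(n_paths ~ disease, data = per_rule, FUN = sum)
    agg[order(-agg$n_paths, agg$disease, method = "radix"), , drop = FALSE]
  } else data.frame(disease = character(0), n_paths = integer(0))
  rownames(totals) <- NULL

  group_counts <- table(factor(vapply(records, `[[`, character(1), "group"),
                               levels = WENDI_GROUPS))

  structure(list(
    xml = build_wendi_xml(records),
    gene_lexicon = gene_lex,
    disease_lexicon = disease_lex,
    go_lexicon = go_lex,
    go_annotation = go_ann,
    gene_disease = gd,
    ground_truth = list(per_rule = per_rule, totals = totals,
                        expected_order = totals$disease,
                        n_records = as.list(group_counts),
                        decoy_genes = decoy_genes),
    config = config
  ), class = "synthetic_dataset")
}

build_wendi_xml <- function(records, query = "querycmpd", smiles = "C") {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<wendi query=\"", query, "\" smiles=\"", smiles, "\">"))
  groups <- split(records, vapply(records, `[[`, character(1), "group"))
  for (gname in WENDI_GROUPS) {
    recs <- groups[[gname]]
    if (is.null(recs)) next
    lines <- c(lines, paste0("  <group name=\"", gname, "\">"))
    for (r in recs) {
      open <- paste0("    <record cid=\"", r$cid, "\" similarity=\"", r$sim, "\"",
                     if (!is.null(r$name)) paste0(" name=\"", xml_escape(r$name), "\""),
                     ">")
      payload <- switch(gname,
        ActiveBioassay = paste0("      <bioassay aid=\"", r$aid, "\" description=\"",
                                xml_escape(r$description), "\"/>"),
        CTD = paste0("      <disease id=\"", r$disease, "\" provenance=\"",
                     r$provenance, "\"/>"),
        Chembl = paste0("      <target gene=\"", r$gene, "\"/>"),
        Literature = paste0("      <article id=\"", r$article, "\" title=\"",
                            xml_escape(r$title), "\">", xml_escape(r$abstract),
                            "</article>")
      )
      lines <- c(lines, open, payload, "    </record>")
    }
    lines <- c(lines, "  </group>")
  }
  paste0(paste(c(lines, "</wendi>"), collapse = "\n"), "\n")
}

#' Write a synthetic dataset to a directory
#'
#' Emits `wendi.xml`, `genes.tsv`, `diseases.tsv`, `go.tsv`,
#' `go_annotation.tsv`, `gene_disease.tsv` and `ground_truth.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(dataset$xml, file.path(dir, "wendi.xml"), sep = "")
  write_tsv <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(as.data.frame(dataset$gene_lexicon), "genes.tsv")
  write_tsv(as.data.frame(dataset$disease_lexicon), "diseases.tsv")
  write_tsv(as.data.frame(dataset$go_lexicon), "go.tsv")
  write_tsv(dataset$go_annotation, "go_annotation.tsv")
  write_tsv(dataset$gene_disease, "gene_disease.tsv")
  jsonlite::write_json(dataset$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

## ---- worked-example fixtures --------------------------------------------------

#' The Methysergide worked-example graph
#'
#' The three RDF statement blocks of the worked Methysergide example,
#' transcribed as printed (27 triples): two literature-channel similar
#' compounds (Methysergide itself at similarity "1.000" and Metergoline at
#' "0.774") co-occurring with gene HTR1B, which the gene-disease matrix links
#' to Autistic_Disorder; and one bioassay-channel compound (similarity
#' "0.929") active in assay aid410 ("p450-cyp1a2"), whose description yields
#' gene CYP1A2, linked to Lymphoma. `isAssociatedWith` is stored gene-to-
#' disease throughout, matching the ontology's domain/range declaration.
#'
#' @return A `kg` with 27 triples that passes [kg_validate()] cleanly.
#' @export
table3_fixture <- function() {
  lit <- literal
  ts <- list(
    triple("wo:querycmpd", "rdf:type", "wo:ChemicalCompound"),
    ## block 1: Methysergide itself, literature channel via HTR1B
    triple("wo:ctdcid9681", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:querycmpd", "wo:isSimilarTo", "wo:ctdcid9681"),
    triple("wo:ctdcid9681", "wo:hasSimilarity", lit("1.000")),
    triple("wo:ctdcid9681", "wo:hasName", lit("Methysergide")),
    triple("wo:HTR1B", "rdf:type", "wo:Gene"),
    triple("wo:HTR1B", "wo:isrelatedTo", "wo:ctdcid9681"),
    triple("wo:HTR1B", "wo:isInferredFrom", lit("pubmedid8743744")),
    triple("wo:Autistic_Disorder", "rdf:type", "wo:Disease"),
    triple("wo:HTR1B", "wo:isAssociatedWith", "wo:Autistic_Disorder"),
    triple("wo:Autistic_Disorder", "wo:isInferredFrom", lit("pubmedid19038234")),
    ## block 2: Metergoline, same gene, a second evidence path
    triple("wo:ctdcid11865408", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:querycmpd", "wo:isSimilarTo", "wo:ctdcid11865408"),
    triple("wo:ctdcid11865408", "wo:hasSimilarity", lit("0.774")),
    triple("wo:ctdcid11865408", "wo:hasName", lit("Metergoline")),
    triple("wo:HTR1B", "wo:isrelatedTo", "wo:ctdcid11865408"),
    triple("wo:HTR1B", "wo:isInferredFrom", lit("pubmedid1330643")),
    ## block 3: bioassay channel via CYP1A2
    triple("wo:cid5486180", "rdf:type", "wo:ChemicalCompound"),
    triple("wo:querycmpd", "wo:isSimilarTo", "wo:cid5486180"),
    triple("wo:cid5486180", "wo:hasSimilarity", lit("0.929")),
    triple("wo:cid5486180", "wo:isActiveIn", "wo:aid410"),
    triple("wo:aid410", "rdf:type", "wo:BioAssay"),
    triple("wo:aid410", "wo:hasName", lit("p450-cyp1a2")),
    triple("wo:CYP1A2", "rdf:type", "wo:Gene"),
    triple("wo:aid410", "wo:hasGene", "wo:CYP1A2"),
    triple("wo:CYP1A2", "wo:isAssociatedWith", "wo:Lymphoma"),
    triple("wo:Lymphoma", "rdf:type", "wo:Disease")
  )
  kg_add_triples(kg_new(), ts)
}

TABLE4_TITLES <- c(
  "First Pharmacophoric Hypothesis for 5-HT7 Antagonism",
  paste0("Novel, Potent, and Selective 5-HT3 Receptor Antagonists Based on ",
         "the Arylpiperazine Skeleton: Synthesis, Structure, Biological ",
         "Activity, and Comparative Molecular Field Analysis Studies"),
  paste0("Synthesis of 2-Piperazinylbenzothiazole and 2-Piperazinylbenzoxazole ",
         "Derivatives with 5-HT3 Antagonist and 5-HT4 Agonist Properties"),
  "Novel and Highly Potent 5-HT3 Receptor Agonists Based on a Pyrroloquinoxaline Structure"
)

#' The serotonin-receptor query fixture
#'
#' A literature graph for the stepwise query-builder scenario: four articles
#' carrying the worked example's serotonin ("5-HT") receptor titles, each
#' reached from a chemical compound via `isContainedIn`, plus two distractor
#' articles whose titles do not mention "5-HT".
#'
#' @return A `kg`.
#' @export
table4_fixture <- function() {
  titles <- c(TABLE4_TITLES,
              "Synthesis of Dopamine D2 Receptor Ligands from Ergoline Scaffolds",
              "A Comparative Study of Serotonergic Radioligand Binding Assays")
  g <- kg_new()
  ts <- list(triple("wo:querycmpd", "rdf:type", "wo:ChemicalCompound"))
  for (i in seq_along(titles)) {
    cid <- paste0("wo:cid77", 1000 + i)
    art <- paste0("wo:pubmedid99", 20000 + i)
    ts <- c(ts, list(
      triple(cid, "rdf:type", "wo:ChemicalCompound"),
      triple("wo:querycmpd", "wo:isSimilarTo", cid),
      triple(cid, "wo:hasSimilarity", literal(fmt_sim(0.95 - 0.03 * i))),
      triple(cid, "wo:isContainedIn", art),
      triple(art, "rdf:type", "wo:JournalArticle"),
      triple(art, "wo:hasTitle", literal(titles[[i]]))
    ))
  }
  kg_add_triples(g, ts)
}
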