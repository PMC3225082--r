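## Independent oracles and random-input builders for property-style tests.
## The oracles deliberately use naive backtracking scans (not the package's
## merge joins) so the two code paths are independent.

binding_sig <- function(named_values) {
  paste(sort(paste0(names(named_values), "=", unlist(named_values))), collapse = "|")
}

## engine bindings data frame -> sorted set of signatures
bindings_sigs <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(unique(vapply(seq_len(nrow(df)), function(i) {
    binding_sig(as.list(df[i, , drop = FALSE]))
  }, character(1))))
}

## naive backtracking conjunctive matcher
oracle_match_body <- function(graph, body) {
  df <- kg_triples(graph)
  results <- character(0)
  by_pred <- split(seq_len(nrow(df)), df$p)
  candidate_rows <- function(pat) {
    if (startsWith(pat$p, "?")) seq_len(nrow(df)) else by_pred[[pat$p]]
  }
  recurse <- function(i, binding) {
    if (i > length(body)) {
      results[[length(results) + 1L]] <<- binding_sig(binding)
      return(invisible(NULL))
    }
    pat <- body[[i]]
    for (r in candidate_rows(pat)) {
      b <- binding
      ok <- TRUE
      for (pos in c("s", "p", "o")) {
        slot <- pat[[pos]]
        val <- df[[pos]][[r]]
        if (startsWith(slot, "?")) {
          nm <- substring(slot, 2L)
          if (!is.null(b[[nm]])) {
            if (b[[nm]] != val) { ok <- FALSE; break }
          } else {
            b[[nm]] <- val
          }
        } else if (slot != val) { ok <- FALSE; break }
      }
      if (ok) recurse(i + 1L, b)
    }
  }
  recurse(1L, list())
  sort(unique(results))
}

## naive repeat-until-no-change fixpoint with path bookkeeping
oracle_forward_chain <- function(graph, rules, max_iter = 200L) {
  df <- kg_triples(graph)
  triples <- unique(paste(df$s, df$p, df$o, sep = " "))
  path_ids <- character(0)
  ground <- function(slot, b) if (startsWith(slot, "?")) b[[substring(slot, 2L)]] else slot
  repeat {
    changed <- FALSE
    g <- kg_new()
    if (length(triples) > 0L) {
      ## subjects/predicates never contain spaces; the object is the remainder
      g$triples <- data.frame(
        s = sub("^(\\S+) .*$", "\\1", triples),
        p = sub("^\\S+ (\\S+) .*$", "\\1", triples),
        o = sub("^\\S+ \\S+ ", "", triples),
        stringsAsFactors = FALSE)
    }
    for (r in rules) {
      sigs <- oracle_match_body(g, r$body)
      for (sig in sigs) {
        pid <- paste0(r$id, "::", sig)
        if (pid %in% path_ids) next
        path_ids <- c(path_ids, pid)
        b <- list()
        if (nzchar(sig)) {
          for (kv in strsplit(sig, "|", fixed = TRUE)[[1]]) {
            eq <- regexpr("=", kv, fixed = TRUE)
            b[[substring(kv, 1L, eq - 1L)]] <- substring(kv, eq + 1L)
          }
        }
        for (h in r$head) {
          key <- paste(ground(h$s, b), ground(h$p, b), ground(h$o, b), sep = " ")
          if (!(key %in% triples)) triples <- c(triples, key)
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(triples = sort(triples), path_ids = sort(path_ids))
}

result_triples <- function(result) {
  df <- kg_triples(result$graph)
  sort(paste(df$s, df$p, df$o, sep = " "))
}

result_path_ids <- function(result) {
  sort(vapply(result$paths, function(p) {
    paste0(p$rule_id, "::", binding_sig(as.list(p$binding)))
  }, character(1)))
}

## ---- random inputs ------------------------------------------------------------

RANDOM_PREDICATES <- c("wo:isSimilarTo", "wo:isActiveIn", "wo:isContainedIn",
                       "wo:hasGene", "wo:hasDisease", "wo:isAssociatedWith",
                       "wo:isrelatedTo", "wo:mightHasDisease", "wo:linksTo",
                       "wo:derivesFrom")

RANDOM_LITERALS <- c("\"0.774\"", "\"plain text\"", "\"quote \\\" inside\"",
                     "\"back\\\\slash\"", "\"tab\\there\"", "\"line\\nbreak\"",
                     "\"5-HT receptor; comma, dot.\"")

random_graph <- function(n_triples, n_nodes = max(6L, n_triples %/% 3L),
                         literal_frac = 0.2) {
  nodes <- paste0("wo:n", seq_len(n_nodes))
  s <- sample(nodes, n_triples, replace = TRUE)
  p <- sample(RANDOM_PREDICATES, n_triples, replace = TRUE)
  o <- ifelse(stats::runif(n_triples) < literal_frac,
              sample(RANDOM_LITERALS, n_triples, replace = TRUE),
              sample(nodes, n_triples, replace = TRUE))
  ts <- lapply(seq_len(n_triples), function(i) triple(s[[i]], p[[i]], o[[i]]))
  kg_add_triples(kg_new(), ts)
}

random_pattern <- function(graph, var_frac = 0.5) {
  df <- kg_triples(graph)
  vars <- c("?x", "?y", "?z")
  pick <- function(pool, var) {
    if (stats::runif(1) < var_frac) var else sample(pool, 1L)
  }
  triple_pattern(pick(unique(df$s), vars[[1]]),
                 pick(unique(df$p), vars[[2]]),
                 pick(unique(c(df$o, df$s)), vars[[3]]))
}

## random range-restricted rule over the shared predicate vocabulary;
## head subjects come from body subject positions so inferred subjects stay IRIs
random_safe_rule <- function(id, n_body = sample(1:3, 1L)) {
  vars <- c("?A", "?B", "?C", "?D")
  nodes <- paste0("wo:n", 1:8)
  body <- lapply(seq_len(n_body), function(i) {
    s <- if (stats::runif(1) < 0.8) sample(vars, 1L) else sample(nodes, 1L)
    o <- if (stats::runif(1) < 0.7) sample(vars, 1L) else sample(nodes, 1L)
    triple_pattern(s, sample(RANDOM_PREDICATES, 1L), o)
  })
  subj_vars <- unlist(lapply(body, function(pat) if (startsWith(pat$s, "?")) pat$s))
  body_vars <- unlist(lapply(body, pattern_vars_pub))
  hs <- if (length(subj_vars) > 0L) sample(subj_vars, 1L) else sample(nodes, 1L)
  ho <- if (length(body_vars) > 0L && stats::runif(1) < 0.8) {
    sample(body_vars, 1L)
  } else sample(nodes, 1L)
  rule(id, body, list(triple_pattern(hs, sample(RANDOM_PREDICATES, 1L), ho)))
}

## pattern_vars is internal to the package; reimplement for the helper
pattern_vars_pub <- function(pat) {
  slots <- c(pat$s, pat$p, pat$o)
  unique(slots[startsWith(slots, "?")])
}

## ---- fixtures -------------------------------------------------------------------

methysergide_inputs <- function() {
  dir <- system.file("extdata", "methysergide", package = "evipath")
  list(
    xml = file.path(dir, "wendi.xml"),
    genes = read_lexicon(file.path(dir, "genes.tsv"), "gene"),
    diseases = read_lexicon(file.path(dir, "diseases.tsv"), "disease"),
    go = read_lexicon(file.path(dir, "go.tsv"), "go_term"),
    go_ann = read_go_annotation(file.path(dir, "go_annotation.tsv")),
    matrix = read_gene_disease_matrix(file.path(dir, "gene_disease.tsv"))
  )
}

methysergide_graph <- function() {
  inp <- methysergide_inputs()
  wendi_to_triples(parse_wendi_xml(inp$xml), inp$genes, inp$diseases, inp$go,
                   inp$go_ann, inp$matrix)
}

## the two-step serotonin-title query used across test files
serotonin_spec <- function() {
  spec <- query_spec()
  spec <- add_step(spec, "ChemicalCompound", "isContainedIn", obj_class("JournalArticle"))
  add_step(spec, "JournalArticle", "hasTitle", obj_contains("5-HT"))
}

## random generator configs for recovery tests
random_generator_config <- function(seed) {
  set.seed(seed)
  n_plants <- sample(1:3, 1L)
  planted <- lapply(seq_len(n_plants), function(i) {
    channels <- lapply(seq_len(sample(1:2, 1L)), function(j) {
      list(channel = sample(c("bioassay", "literature", "ctd", "chembl"), 1L),
           multiplicity = sample(1:4, 1L))
    })
    list(disease = NULL, channels = channels)
  })
  generator_config(
    n_similar_compounds = 60L, n_bioassays = 30L, n_genes = 40L,
    n_diseases = 10L, n_articles = 40L,
    planted = planted,
    decoy_fraction = stats::runif(1, 0, 0.4),
    go_fraction = sample(c(0, 0.5), 1L),
    seed = seed + 1000L
  )
}

run_generated <- function(ds) {
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp))
  writeLines(ds$xml, tmp, sep = "")
  g <- wendi_to_triples(parse_wendi_xml(tmp), ds$gene_lexicon, ds$disease_lexicon,
                        ds$go_lexicon, ds$go_annotation, ds$gene_disease)
  forward_chain(g, default_rules())
}
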