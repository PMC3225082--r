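## Clustering, ranking and faceted filtering of evidence paths.

path_disease <- function(p) {
  hit <- p$inferred[p$inferred$p == "wo:mightHasDisease", , drop = FALSE]
  if (nrow(hit) == 0L) return(NA_character_)
  hit$o[[1L]]
}

paths_of <- function(x) {
  if (inherits(x, "inference_result") || inherits(x, "path_set")) return(x$paths)
  if (inherits(x, "evidence_path")) return(list(x))
  if (is.list(x)) return(x)
  stop("expected an inference_result, path_set or list of evidence paths", call. = FALSE)
}

types_of <- function(x) {
  if (inherits(x, "inference_result")) return(node_types(x$graph))
  if (inherits(x, "path_set")) return(x$node_types)
  character(0)
}

#' Cluster evidence paths by disease
#'
#' Partitions the paths of an inference result by the disease named in their
#' inferred `mightHasDisease` head.
#'
#' @param result An `inference_result` (or `path_set`).
#' @return List of `disease_cluster` objects (`disease` node key, `paths`),
#'   one per distinct inferred disease, ordered by disease key.
#' @export
cluster_by_disease <- function(result) {
  paths <- paths_of(result)
  if (length(paths) == 0L) return(list())
  dis <- vapply(paths, path_disease, character(1))
  keep <- !is.na(dis)
  paths <- paths[keep]; dis <- dis[keep]
  out <- lapply(sort(unique(dis)), function(d) {
    structure(list(disease = d, paths = paths[dis == d]), class = "disease_cluster")
  })
  out
}

#' @export
print.disease_cluster <- function(x, ...) {
  cat("<disease cluster ", x$disease, ": ", length(x$paths), " paths>\n", sep = "")
  invisible(x)
}

#' Rank disease clusters
#'
#' `path_count` scores a cluster by its number of evidence paths (the
#' intended ranking: more independent evidence, higher rank).
#' `property_count` reproduces the literal aggregate query over the
#' materialized graph -- the number of (predicate, object) statements whose
#' subject is the disease node, including housekeeping predicates such as
#' `rdf:type` and `isInferredFrom`. The two metrics can legitimately
#' disagree: distinct paths may share triples, which collapse under set
#' semantics. Ordering is by descending score with a lexicographic tie-break
#' on the disease key; ranks are 1..N without gaps.
#'
#' @param clusters List of `disease_cluster` from [cluster_by_disease()].
#' @param metric `"path_count"` (default) or `"property_count"`.
#' @param graph Materialized `kg`; required for `property_count`.
#' @return A `ranked_associations` object: data frame with columns `disease`
#'   (local name), `score`, `metric`, `rank`, carrying the clusters and graph
#'   as attributes for downstream JSON export.
#' @export
rank_clusters <- function(clusters, metric = c("path_count", "property_count"),
                          graph = NULL) {
  if (!is.character(metric) || !all(metric %in% c("path_count", "property_count"))) {
    stop("unknown ranking metric: ", paste(setdiff(metric, c("path_count", "property_count")),
                                           collapse = ", "), call. = FALSE)
  }
  metric <- match.arg(metric)
  if (metric == "property_count" && !is_kg(graph)) {
    stop("property_count ranking needs the materialized graph", call. = FALSE)
  }
  if (length(clusters) == 0L) {
    out <- data.frame(disease = character(0), score = numeric(0),
                      metric = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
    return(structure(out, clusters = list(), graph = graph,
                     class = c("ranked_associations", "data.frame")))
  }
  dis <- vapply(clusters, function(cl) cl$disease, character(1))
  score <- switch(metric,
    path_count = vapply(clusters, function(cl) length(cl$paths), numeric(1)),
    property_count = vapply(dis, function(d) sum(graph$triples$s == d), numeric(1))
  )
  ord <- order(-score, dis, method = "radix")
  out <- data.frame(disease = sub("^wo:", "", dis[ord]), score = score[ord],
                    metric = metric, rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  structure(out, clusters = clusters[ord], graph = graph,
            class = c("ranked_associations", "data.frame"))
}

#' Cluster and rank in one step
#' @param result An `inference_result`.
#' @inheritParams rank_clusters
#' @return A `ranked_associations`.
#' @export
rank_diseases <- function(result, metric = "path_count") {
  rank_clusters(cluster_by_disease(result), metric = metric, graph = result$graph)
}

## ---- faceted filtering -------------------------------------------------------

FACET_CLASSES <- c(disease = "Disease", compound = "ChemicalCompound",
                   assay = "BioAssay", gene = "Gene", journal = "JournalArticle")

path_nodes <- function(p) {
  unique(c(unname(p$binding),
           p$grounded_body$s, p$grounded_body$o,
           p$inferred$s, p$inferred$o))
}

#' Filter evidence paths by facet
#'
#' Keeps the paths in which `value` plays the facet's role: a node of the
#' facet's class (disease, compound, assay, gene, journal) appearing in the
#' path's binding, grounded body or inferred head. Filters compose by
#' intersection: applying two facets keeps paths satisfying both. The
#' `gene_family` facet is available only when a gene-to-family table is
#' supplied (`families`, columns `gene` and `family`); it keeps paths
#' mentioning any gene of the family.
#'
#' @param x An `inference_result` or `path_set`.
#' @param facet One of `"disease"`, `"compound"`, `"assay"`, `"gene"`,
#'   `"journal"`, `"gene_family"`.
#' @param value Facet value: a node name (`"Autistic_Disorder"`, `"wo:aid410"`)
#'   or, for `journal`, optionally a title literal (resolved against the graph
#'   of an `inference_result`).
#' @param families Optional gene-family data frame, required for `gene_family`.
#' @return `x` with its paths filtered (same class).
#' @export
facet_filter <- function(x, facet, value, families = NULL) {
  facet <- match.arg(facet, c(names(FACET_CLASSES), "gene_family"))
  paths <- paths_of(x)
  types <- types_of(x)

  if (facet == "gene_family") {
    if (is.null(families)) {
      stop("the gene_family facet needs a gene-to-family table (families=)", call. = FALSE)
    }
    members <- paste0("wo:", sub("^wo:", "", families$gene[families$family == value]))
    keep <- vapply(paths, function(p) any(members %in% path_nodes(p)), logical(1))
    return(replace_paths(x, paths[keep]))
  }

  key <- value
  if (!startsWith(key, "\"") && !grepl(":", key, fixed = TRUE)) key <- paste0("wo:", key)
  if (startsWith(key, "\"") && facet == "journal") {
    ## title literal: resolve to the article nodes carrying it
    if (!inherits(x, "inference_result")) {
      stop("a journal-title literal can only be resolved against an inference_result",
           call. = FALSE)
    }
    df <- x$graph$triples
    nodes <- df$s[df$p == "wo:hasTitle" & df$o == key]
    keep <- vapply(paths, function(p) any(nodes %in% path_nodes(p)), logical(1))
    return(replace_paths(x, paths[keep]))
  }
  wanted_class <- FACET_CLASSES[[facet]]
  typed_ok <- !is.na(types[key]) && identical(unname(types[key]), wanted_class)
  if (!typed_ok) return(replace_paths(x, list()))
  keep <- vapply(paths, function(p) key %in% path_nodes(p), logical(1))
  replace_paths(x, paths[keep])
}

replace_paths <- function(x, paths) {
  if (inherits(x, "inference_result") || inherits(x, "path_set")) {
    x$paths <- paths
    return(x)
  }
  paths
}

## ---- result JSON ---------------------------------------------------------------

local_name <- function(key) sub("^wo:", "", key)

literal_value <- function(key) {
  if (!key_is_literal(key)) return(key)
  key_to_term(key)$value
}

path_record <- function(p, graph, types) {
  df <- graph$triples
  bvals <- unname(p$binding)
  typed <- function(class) {
    hits <- bvals[!is.na(types[bvals]) & types[bvals] == class]
    if (length(hits) == 0L) NULL else hits[[1L]]
  }
  sim_triples <- p$grounded_body[p$grounded_body$p == "wo:isSimilarTo", , drop = FALSE]
  compound <- if (nrow(sim_triples) > 0L) sim_triples$o[[1L]] else typed("ChemicalCompound")
  similarity <- if (!is.null(compound)) {
    hit <- df$o[df$s == compound & df$p == "wo:hasSimilarity"]
    if (length(hit) > 0L) literal_value(hit[[1L]]) else NULL
  }
  gene <- typed("Gene"); assay <- typed("BioAssay"); article <- typed("JournalArticle")
  prov_nodes <- c(gene, path_disease(p))
  provenance <- unique(vapply(
    df$o[df$s %in% prov_nodes & df$p == "wo:isInferredFrom"],
    literal_value, character(1)))
  rec <- list(rule = p$rule_id)
  rec$similar_compound <- if (!is.null(compound)) local_name(compound) else NULL
  rec$similarity <- similarity
  rec$gene <- if (!is.null(gene)) local_name(gene) else NULL
  rec$bioassay <- if (!is.null(assay)) local_name(assay) else NULL
  rec$article <- if (!is.null(article)) local_name(article) else NULL
  rec$provenance <- as.list(provenance)
  rec
}

#' Export a ranking as the result JSON document
#'
#' An ordered array of `{disease, score, paths: [...]}` objects with a stable
#' field order; each path record carries its rule id, the supporting similar
#' compound with its verbatim similarity string, the intermediate gene /
#' bioassay / article where the rule binds one, and the provenance strings
#' (publication identifiers) attached to the path's gene and disease. The
#' document validates against the schema shipped at
#' `inst/extdata/schemas/result.schema.json` (see [validate_result_json()]).
#'
#' @param ranked A `ranked_associations` from [rank_clusters()].
#' @param file Optional output path.
#' @return JSON text (invisibly when `file` is given).
#' @export
to_result_json <- function(ranked, file = NULL) {
  stopifnot(inherits(ranked, "ranked_associations"))
  clusters <- attr(ranked, "clusters")
  graph <- attr(ranked, "graph")
  types <- if (is_kg(graph)) node_types(graph) else character(0)
  empty_graph <- kg_new()
  doc <- lapply(seq_len(nrow(ranked)), function(i) {
    cl <- clusters[[i]]
    list(
      disease = ranked$disease[[i]],
      score = ranked$score[[i]],
      paths = lapply(cl$paths, path_record,
                     graph = if (is_kg(graph)) graph else empty_graph, types = types)
    )
  })
  text <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

#' Validate a result JSON document
#'
#' Structural validation against the shipped result schema: a JSON array of
#' objects with required string `disease`, numeric `score` and non-empty
#' `paths` array, each path an object with required `rule`,
#' `similar_compound` and `provenance` (array of strings) and optional
#' `similarity`, `gene`, `bioassay`, `article` strings, and no other fields.
#'
#' @param text JSON text (or a file path).
#' @return Character vector of violations; empty means valid.
#' @export
validate_result_json <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) e)
  if (inherits(doc, "error")) return(paste("not parseable JSON:", conditionMessage(doc)))
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (!is.list(doc)) return("document must be a JSON array")
  path_required <- c("rule", "similar_compound", "provenance")
  path_allowed <- c("rule", "similar_compound", "similarity", "gene", "bioassay",
                    "article", "provenance")
  for (i in seq_along(doc)) {
    el <- doc[[i]]
    if (!is.list(el)) { note("element ", i, " is not an object"); next }
    for (f in c("disease", "score", "paths")) {
      if (is.null(el[[f]])) note("element ", i, " missing field '", f, "'")
    }
    if (!is.null(el$disease) && !is.character(el$disease)) {
      note("element ", i, ": disease must be a string")
    }
    if (!is.null(el$score) && !is.numeric(el$score)) {
      note("element ", i, ": score must be a number")
    }
    if (!is.null(el$paths)) {
      if (!is.list(el$paths) || length(el$paths) == 0L) {
        note("element ", i, ": paths must be a non-empty array")
      } else {
        for (j in seq_along(el$paths)) {
          pr <- el$paths[[j]]
          miss <- setdiff(path_required, names(pr))
          if (length(miss) > 0L) {
            note("element ", i, " path ", j, " missing ", paste(miss, collapse = ", "))
          }
          extra <- setdiff(names(pr), path_allowed)
          if (length(extra) > 0L) {
            note("element ", i, " path ", j, " has unknown field ",
                 paste(extra, collapse = ", "))
          }
          if (!is.null(pr$provenance) && !is.list(pr$provenance)) {
            note("element ", i, " path ", j, ": provenance must be an array")
          }
        }
      }
    }
  }
  problems
}
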