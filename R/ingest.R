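## Ingest: WENDI-style XML -> record groups -> ontology-conformant triples.

WENDI_GROUPS <- c("ActiveBioassay", "CTD", "Chembl", "Literature")

#' Parse a WENDI-style XML result document
#'
#' The dialect is this package's own (schema shipped at
#' `inst/extdata/schemas/wendi.xsd`): a `<wendi>` root naming the query
#' compound, containing up to four `<group>` elements (ActiveBioassay, CTD,
#' Chembl, Literature), each holding `<record>` elements that carry the
#' similar compound id, its Tanimoto similarity, and a group-specific payload
#' (`<bioassay>`, `<disease>`, `<target>` or `<article>`).
#'
#' @param x XML text or a path to an XML file.
#' @param validate Validate against the shipped XSD first (default TRUE).
#' @return A `wendi_record_set`: list with `query_compound` (id, smiles) and
#'   `groups`, a named list of record lists. Similarities are kept both as
#'   numerics and as their verbatim printed strings.
#' @export
parse_wendi_xml <- function(x, validate = TRUE) {
  doc <- xml2::read_xml(x)
  if (validate) {
    xsd_path <- system.file("extdata", "schemas", "wendi.xsd", package = "evipath")
    if (nzchar(xsd_path)) {
      ok <- xml2::xml_validate(doc, xml2::read_xml(xsd_path))
      if (!isTRUE(ok)) {
        stop("WENDI document violates the schema: ",
             paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
      }
    }
  }
  root <- xml2::xml_root(doc)
  query <- xml2::xml_attr(root, "query")
  if (is.na(query) || !nzchar(query)) stop("missing 'query' attribute on <wendi>", call. = FALSE)
  groups <- stats::setNames(vector("list", length(WENDI_GROUPS)), WENDI_GROUPS)
  groups[] <- list(list())
  for (gnode in xml2::xml_find_all(root, "./group")) {
    gname <- xml2::xml_attr(gnode, "name")
    if (!(gname %in% WENDI_GROUPS)) {
      stop("unknown group name '", gname, "' (line ",
           xml2::xml_path(gnode), "); expected one of ",
           paste(WENDI_GROUPS, collapse = ", "), call. = FALSE)
    }
    recs <- lapply(xml2::xml_find_all(gnode, "./record"), parse_wendi_record, group = gname)
    groups[[gname]] <- c(groups[[gname]], recs)
  }
  structure(list(
    query_compound = list(id = query, smiles = xml2::xml_attr(root, "smiles")),
    groups = groups
  ), class = "wendi_record_set")
}

parse_wendi_record <- function(rnode, group) {
  cid <- xml2::xml_attr(rnode, "cid")
  sim_chr <- xml2::xml_attr(rnode, "similarity")
  sim <- suppressWarnings(as.numeric(sim_chr))
  if (is.na(cid) || is.na(sim)) {
    stop("record in group ", group, " at ", xml2::xml_path(rnode),
         " is missing cid or similarity", call. = FALSE)
  }
  if (sim < 0 || sim > 1) {
    stop("record ", cid, ": similarity ", sim_chr, " outside [0,1]", call. = FALSE)
  }
  payload_node <- xml2::xml_child(rnode)
  expected <- switch(group, ActiveBioassay = "bioassay", CTD = "disease",
                     Chembl = "target", Literature = "article")
  if (inherits(payload_node, "xml_missing") ||
      xml2::xml_name(payload_node) != expected) {
    stop("record ", cid, " in group ", group, " must carry a <", expected,
         "> payload (", xml2::xml_path(rnode), ")", call. = FALSE)
  }
  payload <- switch(group,
    ActiveBioassay = list(kind = "bioassay",
                          aid = xml2::xml_attr(payload_node, "aid"),
                          description = xml2::xml_attr(payload_node, "description")),
    CTD = list(kind = "ctd_disease",
               disease = xml2::xml_attr(payload_node, "id"),
               provenance = xml2::xml_attr(payload_node, "provenance")),
    Chembl = list(kind = "chembl_activity",
                  gene = xml2::xml_attr(payload_node, "gene")),
    Literature = list(kind = "literature",
                      article = xml2::xml_attr(payload_node, "id"),
                      title = xml2::xml_attr(payload_node, "title"),
                      abstract = xml2::xml_text(payload_node))
  )
  list(similar_compound = cid, name = xml2::xml_attr(rnode, "name"),
       similarity = sim, similarity_chr = sim_chr,
       group = group, payload = payload)
}

#' @export
print.wendi_record_set <- function(x, ...) {
  counts <- vapply(x$groups, length, integer(1))
  cat("<WENDI record set for ", x$query_compound$id, ": ",
      paste(names(counts), counts, sep = "=", collapse = ", "), ">\n", sep = "")
  invisible(x)
}

## ---- side tables -------------------------------------------------------------

#' Read a term lexicon (TSV: term <tab> id, with header)
#' @param file Path.
#' @param kind One of `"gene"`, `"disease"`, `"go_term"`.
#' @return A `ce_lexicon`: data frame `term`/`id` with a `kind` attribute.
#' @export
read_lexicon <- function(file, kind = c("gene", "disease", "go_term")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("term", "id") %in% names(df))) {
    stop("lexicon ", file, " must have 'term' and 'id' columns", call. = FALSE)
  }
  lexicon(df$term, df$id, kind)
}

#' Build a lexicon in code
#' @param term Surface forms (non-empty strings).
#' @param id Entity identifiers, parallel to `term`.
#' @param kind Entity kind of the whole lexicon.
#' @return A `ce_lexicon`.
#' @export
lexicon <- function(term, id, kind = c("gene", "disease", "go_term")) {
  kind <- match.arg(kind)
  if (any(!nzchar(term))) stop("lexicon surface terms must be non-empty", call. = FALSE)
  structure(data.frame(term = term, id = id, stringsAsFactors = FALSE),
            kind = kind, class = c("ce_lexicon", "data.frame"))
}

#' Read a GO-term to gene annotation table (TSV: go_id <tab> gene)
#' @param file Path.
#' @return Data frame `go_id`/`gene`.
#' @export
read_go_annotation <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("go_id", "gene") %in% names(df))) {
    stop("GO annotation ", file, " must have 'go_id' and 'gene' columns", call. = FALSE)
  }
  df
}

#' Read a gene-disease association matrix (TSV: gene, disease, provenance?)
#' @param file Path.
#' @return Data frame `gene`/`disease`/`provenance` (provenance may be `""`).
#' @export
read_gene_disease_matrix <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("gene", "disease") %in% names(df))) {
    stop("matrix ", file, " must have 'gene' and 'disease' columns", call. = FALSE)
  }
  if (is.null(df$provenance)) df$provenance <- ""
  df[c("gene", "disease", "provenance")]
}

## ---- annotation operations ---------------------------------------------------

#' Dictionary term extraction
#'
#' Finds every lexicon surface term occurring in `text`. The default is
#' case-insensitive plain substring matching (the behaviour of a SQL
#' `position()` lookup); `word_boundary = TRUE` additionally requires the
#' term to sit on word boundaries, which suppresses gene symbols embedded in
#' longer words. All matches are reported; there is no longest-match
#' suppression.
#'
#' @param text A single string (empty allowed).
#' @param lex A `ce_lexicon`.
#' @param word_boundary Require matches to start/end at word boundaries.
#' @param ignore_case Case-insensitive matching (default TRUE).
#' @return Data frame `id`/`term`/`offset` (1-based offset of the first
#'   occurrence), ordered by offset then term.
#' @export
extract_terms <- function(text, lex, word_boundary = FALSE, ignore_case = TRUE) {
  stopifnot(inherits(lex, "ce_lexicon"))
  empty <- data.frame(id = character(0), term = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  if (length(text) == 0L || is.na(text) || !nzchar(text) || nrow(lex) == 0L) return(empty)
  hay <- if (ignore_case) tolower(text) else text
  needles <- if (ignore_case) tolower(lex$term) else lex$term
  offs <- integer(nrow(lex))
  for (i in seq_len(nrow(lex))) {
    if (word_boundary) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", needles[[i]]), "\\b")
      offs[[i]] <- regexpr(pat, hay, perl = TRUE)
    } else {
      offs[[i]] <- regexpr(needles[[i]], hay, fixed = TRUE)
    }
  }
  hit <- offs > 0L
  out <- data.frame(id = lex$id[hit], term = lex$term[hit], offset = offs[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand GO terms to their annotated genes
#' @param terms Character vector of GO-term ids.
#' @param ann GO annotation data frame (`go_id`, `gene`).
#' @return Character vector: union of gene sets; unknown terms contribute nothing.
#' @export
go_terms_to_genes <- function(terms, ann) {
  if (length(terms) == 0L) return(character(0))
  sort(unique(ann$gene[ann$go_id %in% terms]))
}

#' Look up disease associations for a gene set
#' @param genes Character vector of gene ids.
#' @param matrix Gene-disease data frame (`gene`, `disease`, `provenance`).
#' @return The matrix rows whose gene is in `genes`.
#' @export
genes_to_diseases <- function(genes, matrix) {
  out <- matrix[matrix$gene %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- triple emission ---------------------------------------------------------

#' Convert a WENDI record set to an ontology-conformant knowledge graph
#'
#' Every record yields `querycmpd isSimilarTo C`, `C hasSimilarity s` (the
#' verbatim printed similarity string) and a `ChemicalCompound` typing, plus
#' group-specific triples:
#' \itemize{
#'   \item ActiveBioassay: `C isActiveIn A`, assay typing and `hasName`;
#'     genes found in the description (directly via the gene lexicon or via
#'     GO terms and the GO annotation) become `A hasGene g`; disease terms in
#'     the description become `A isAssociatedWith dis`.
#'   \item CTD: `C hasDisease dis` directly, with `dis isInferredFrom`
#'     provenance when supplied.
#'   \item Chembl: `C hasGene g`.
#'   \item Literature: `C isContainedIn J`, `J hasTitle t`; genes found in
#'     title/abstract become `g isrelatedTo C` with `g isInferredFrom` the
#'     article id; disease terms become `J hasDisease dis`.
#' }
#' Every emitted gene additionally pulls its matrix associations:
#' `g isAssociatedWith dis` plus `dis isInferredFrom` the row's provenance.
#'
#' @param records A `wendi_record_set`.
#' @param gene_lex,disease_lex,go_lex Lexicons (see [lexicon()]).
#' @param go_ann GO annotation data frame.
#' @param gd_matrix Gene-disease matrix data frame.
#' @param word_boundary Passed to [extract_terms()].
#' @return A `kg` that passes [kg_validate()] with zero violations.
#' @export
wendi_to_triples <- function(records, gene_lex, disease_lex, go_lex, go_ann,
                             gd_matrix, word_boundary = FALSE) {
  stopifnot(inherits(records, "wendi_record_set"))
  rows <- list()
  emit <- function(s, p, o) rows[[length(rows) + 1L]] <<- c(s = s, p = p, o = o)
  lit <- function(x) term_key(literal(x))
  wo <- function(x) paste0("wo:", x)

  query <- wo(records$query_compound$id)
  emit(query, "rdf:type", "wo:ChemicalCompound")

  emit_gene_diseases <- function(gene_ids) {
    assoc <- genes_to_diseases(gene_ids, gd_matrix)
    for (k in seq_len(nrow(assoc))) {
      emit(wo(assoc$gene[[k]]), "wo:isAssociatedWith", wo(assoc$disease[[k]]))
      emit(wo(assoc$disease[[k]]), "rdf:type", "wo:Disease")
      if (nzchar(assoc$provenance[[k]])) {
        emit(wo(assoc$disease[[k]]), "wo:isInferredFrom", lit(assoc$provenance[[k]]))
      }
    }
  }

  for (group in names(records$groups)) {
    for (rec in records$groups[[group]]) {
      C <- wo(rec$similar_compound)
      emit(C, "rdf:type", "wo:ChemicalCompound")
      emit(query, "wo:isSimilarTo", C)
      emit(C, "wo:hasSimilarity", lit(rec$similarity_chr))
      if (!is.na(rec$name) && nzchar(rec$name)) emit(C, "wo:hasName", lit(rec$name))
      pl <- rec$payload
      if (group == "ActiveBioassay") {
        A <- wo(pl$aid)
        emit(C, "wo:isActiveIn", A)
        emit(A, "rdf:type", "wo:BioAssay")
        emit(A, "wo:hasName", lit(pl$description))
        direct <- extract_terms(pl$description, gene_lex, word_boundary)$id
        via_go <- go_terms_to_genes(extract_terms(pl$description, go_lex, word_boundary)$id,
                                    go_ann)
        genes <- unique(c(direct, via_go))
        for (g in genes) {
          emit(A, "wo:hasGene", wo(g))
          emit(wo(g), "rdf:type", "wo:Gene")
        }
        emit_gene_diseases(genes)
        for (d in unique(extract_terms(pl$description, disease_lex, word_boundary)$id)) {
          emit(A, "wo:isAssociatedWith", wo(d))
          emit(wo(d), "rdf:type", "wo:Disease")
        }
      } else if (group == "CTD") {
        emit(C, "wo:hasDisease", wo(pl$disease))
        emit(wo(pl$disease), "rdf:type", "wo:Disease")
        if (!is.na(pl$provenance) && nzchar(pl$provenance)) {
          emit(wo(pl$disease), "wo:isInferredFrom", lit(pl$provenance))
        }
      } else if (group == "Chembl") {
        emit(C, "wo:hasGene", wo(pl$gene))
        emit(wo(pl$gene), "rdf:type", "wo:Gene")
        emit_gene_diseases(pl$gene)
      } else if (group == "Literature") {
        J <- wo(pl$article)
        emit(C, "wo:isContainedIn", J)
        emit(J, "rdf:type", "wo:JournalArticle")
        if (!is.na(pl$title) && nzchar(pl$title)) emit(J, "wo:hasTitle", lit(pl$title))
        text <- paste(c(pl$title, pl$abstract), collapse = " ")
        genes <- unique(extract_terms(text, gene_lex, word_boundary)$id)
        for (g in genes) {
          emit(wo(g), "wo:isrelatedTo", C)
          emit(wo(g), "rdf:type", "wo:Gene")
          emit(wo(g), "wo:isInferredFrom", lit(pl$article))
        }
        emit_gene_diseases(genes)
        for (d in unique(extract_terms(text, disease_lex, word_boundary)$id)) {
          emit(J, "wo:hasDisease", wo(d))
          emit(wo(d), "rdf:type", "wo:Disease")
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  kg_add_rows(kg_new(), data.frame(s = m[, "s"], p = m[, "p"], o = m[, "o"],
                                   stringsAsFactors = FALSE))
}
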