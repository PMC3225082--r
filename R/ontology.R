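#' The Chemogenomic Explorer ontology
#'
#' Entity classes (ChemicalCompound, BioAssay, JournalArticle, Gene, Disease)
#' and the properties connecting them, with domain/range declarations used by
#' [kg_validate()]. `hasGenes` is accepted as a read-time alias of `hasGene`,
#' and `isSimiliarTo` of `isSimilarTo` (both spellings occur in source data).
#'
#' @return An object of class `ce_ontology` with elements `classes`,
#'   `properties` (each a list with `domain` and `range`; range `"literal"`
#'   marks data properties) and `aliases`.
#' @export
ce_ontology <- function() {
  cls <- c("ChemicalCompound", "BioAssay", "JournalArticle", "Gene", "Disease")
  prop <- function(domain, range) list(domain = domain, range = range)
  properties <- list(
    isSimilarTo      = prop("ChemicalCompound", "ChemicalCompound"),
    isActiveIn       = prop("ChemicalCompound", "BioAssay"),
    isContainedIn    = prop("ChemicalCompound", "JournalArticle"),
    hasGene          = prop(c("BioAssay", "JournalArticle", "ChemicalCompound"), "Gene"),
    hasDisease       = prop(c("BioAssay", "JournalArticle", "ChemicalCompound"), "Disease"),
    isAssociatedWith = prop(c("Gene", "BioAssay"), "Disease"),
    isrelatedTo      = prop("Gene", "ChemicalCompound"),
    hasSimilarity    = prop("ChemicalCompound", "literal"),
    hasName          = prop(c("ChemicalCompound", "BioAssay"), "literal"),
    hasTitle         = prop("JournalArticle", "literal"),
    isInferredFrom   = prop(c("Gene", "Disease"), "literal"),
    mightHasDisease  = prop("ChemicalCompound", "Disease")
  )
  structure(list(
    classes = cls,
    properties = properties,
    aliases = c(hasGenes = "hasGene", isSimiliarTo = "isSimilarTo")
  ), class = "ce_ontology")
}

#' Canonicalize a predicate local name against ontology aliases
#' @param name Predicate local name.
#' @param ontology A `ce_ontology`.
#' @return Canonical local name.
#' @export
canonical_predicate <- function(name, ontology = ce_ontology()) {
  if (name %in% names(ontology$aliases)) unname(ontology$aliases[[name]]) else name
}

## node -> class map from rdf:type triples (first class wins; duplicates are
## reported by kg_validate)
node_types <- function(graph) {
  df <- graph$triples
  ty <- df[df$p == "rdf:type", , drop = FALSE]
  ty <- ty[!duplicated(ty$s), , drop = FALSE]
  stats::setNames(sub("^wo:", "", ty$o), ty$s)
}

#' Validate a graph against the ontology
#'
#' Flags (1) triples whose predicate is neither `rdf:type` nor a declared
#' property, (2) domain violations (typed subject outside the property's
#' domain), (3) range violations (typed object outside the range; literal
#' where an entity is required and vice versa), (4) nodes carrying more than
#' one `rdf:type` among the ontology classes, and (5) `rdf:type` objects that
#' are not ontology classes. Untyped nodes are not flagged (their class is
#' unknown, not wrong).
#'
#' @param graph A `kg`.
#' @param ontology A `ce_ontology`.
#' @return Data frame with columns `s`, `p`, `o`, `issue`; zero rows iff the
#'   graph conforms.
#' @export
kg_validate <- function(graph, ontology = ce_ontology()) {
  stopifnot(is_kg(graph), inherits(ontology, "ce_ontology"))
  df <- graph$triples
  issues <- list()
  flag <- function(rows, issue) {
    if (nrow(rows) > 0L) {
      rows$issue <- issue
      issues[[length(issues) + 1L]] <<- rows
    }
  }
  types <- node_types(graph)

  ## multi-typed nodes
  ty <- df[df$p == "rdf:type", , drop = FALSE]
  multi <- unique(ty$s[duplicated(ty$s)])
  flag(ty[ty$s %in% multi, , drop = FALSE], "node has more than one rdf:type")
  flag(ty[!(sub("^wo:", "", ty$o) %in% ontology$classes), , drop = FALSE],
       "rdf:type object is not an ontology class")

  plain <- df[df$p != "rdf:type", , drop = FALSE]
  local <- sub("^wo:", "", plain$p)
  canon <- vapply(local, canonical_predicate, character(1), ontology = ontology)
  declared <- canon %in% names(ontology$properties)
  flag(plain[!declared, , drop = FALSE], "undeclared predicate")

  ok <- plain[declared, , drop = FALSE]
  okc <- canon[declared]
  for (i in seq_len(nrow(ok))) {
    decl <- ontology$properties[[okc[[i]]]]
    st <- types[ok$s[[i]]]
    if (!is.na(st) && !(st %in% decl$domain)) {
      flag(ok[i, , drop = FALSE],
           paste0("domain violation: subject of ", okc[[i]], " is ", st))
    }
    if (identical(decl$range, "literal")) {
      if (!key_is_literal(ok$o[[i]])) {
        flag(ok[i, , drop = FALSE],
             paste0("range violation: ", okc[[i]], " expects a literal object"))
      }
    } else {
      if (key_is_literal(ok$o[[i]])) {
        flag(ok[i, , drop = FALSE],
             paste0("range violation: ", okc[[i]], " expects an entity object"))
      } else {
        ot <- types[ok$o[[i]]]
        if (!is.na(ot) && !(ot %in% decl$range)) {
          flag(ok[i, , drop = FALSE],
               paste0("range violation: object of ", okc[[i]], " is ", ot))
        }
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(s = character(0), p = character(0), o = character(0),
                      issue = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
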