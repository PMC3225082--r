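#' Create an empty knowledge graph
#'
#' A knowledge graph is an immutable value: a set of subject-predicate-object
#' statements plus a prefix-to-IRI namespace table. All operations return a
#' new graph; none mutate in place.
#'
#' @param namespaces Named character vector of prefix/base-IRI pairs; must
#'   include `wo` and `rdf`.
#' @return A `kg` object with zero triples.
#' @export
kg_new <- function(namespaces = ce_namespaces()) {
  if (!all(c("wo", "rdf") %in% names(namespaces))) {
    stop("namespace table must bind the 'wo' and 'rdf' prefixes", call. = FALSE)
  }
  structure(list(
    triples = data.frame(s = character(0), p = character(0), o = character(0),
                         stringsAsFactors = FALSE),
    namespaces = namespaces
  ), class = "kg")
}

is_kg <- function(x) inherits(x, "kg")

triple_keys <- function(df) paste(df$s, df$p, df$o, sep = " ")

check_term_resolves <- function(t, namespaces) {
  if (t$kind == "iri" && !(t$prefix %in% names(namespaces))) {
    stop("term '", t$prefix, ":", t$value,
         "' uses a prefix not bound in the graph's namespace map", call. = FALSE)
  }
  invisible(TRUE)
}

#' Add a triple to a graph
#'
#' Set semantics: adding a triple already present is a no-op.
#'
#' @param graph A `kg`.
#' @param t A `ce_triple` (or the three positions via `...` shorthand).
#' @return A new `kg` containing `t`.
#' @export
kg_add <- function(graph, t) {
  stopifnot(is_kg(graph))
  if (!inherits(t, "ce_triple")) stop("kg_add expects a ce_triple", call. = FALSE)
  for (slot in t[c("s", "p", "o")]) check_term_resolves(slot, graph$namespaces)
  row <- data.frame(s = term_key(t$s), p = term_key(t$p), o = term_key(t$o),
                    stringsAsFactors = FALSE)
  if (any(triple_keys(graph$triples) == triple_keys(row))) return(graph)
  graph$triples <- rbind(graph$triples, row)
  graph
}

#' Add several triples at once
#'
#' @param graph A `kg`.
#' @param triples List of `ce_triple` objects.
#' @return A new `kg`.
#' @export
kg_add_triples <- function(graph, triples) {
  stopifnot(is_kg(graph))
  if (length(triples) == 0L) return(graph)
  rows <- lapply(triples, function(t) {
    if (!inherits(t, "ce_triple")) stop("kg_add_triples expects ce_triple objects", call. = FALSE)
    for (slot in t[c("s", "p", "o")]) check_term_resolves(slot, graph$namespaces)
    c(term_key(t$s), term_key(t$p), term_key(t$o))
  })
  m <- do.call(rbind, rows)
  df <- rbind(graph$triples,
              data.frame(s = m[, 1], p = m[, 2], o = m[, 3], stringsAsFactors = FALSE))
  graph$triples <- df[!duplicated(triple_keys(df)), , drop = FALSE]
  rownames(graph$triples) <- NULL
  graph
}

## Internal fast path: add rows of node keys (already validated upstream).
kg_add_rows <- function(graph, df) {
  if (nrow(df) == 0L) return(graph)
  all <- rbind(graph$triples, df[, c("s", "p", "o"), drop = FALSE])
  graph$triples <- all[!duplicated(triple_keys(all)), , drop = FALSE]
  rownames(graph$triples) <- NULL
  graph
}

#' Number of triples in a graph
#' @param graph A `kg`.
#' @return Integer count.
#' @export
kg_size <- function(graph) nrow(graph$triples)

#' Is a triple present?
#' @param graph A `kg`.
#' @param t A `ce_triple`.
#' @return Logical.
#' @export
kg_contains <- function(graph, t) {
  key <- paste(term_key(t$s), term_key(t$p), term_key(t$o), sep = " ")
  any(triple_keys(graph$triples) == key)
}

#' Triples as a data frame
#'
#' @param graph A `kg`.
#' @return Data frame with character columns `s`, `p`, `o` holding canonical
#'   node keys (prefixed names for IRIs, quoted strings for literals).
#' @export
kg_triples <- function(graph) graph$triples

#' Set equality of two graphs
#' @param a,b `kg` objects.
#' @return Logical: same triple set (order-insensitive).
#' @export
kg_equal <- function(a, b) {
  setequal(triple_keys(a$triples), triple_keys(b$triples))
}

#' @export
print.kg <- function(x, ...) {
  cat("<knowledge graph: ", kg_size(x), " triples, prefixes: ",
      paste(names(x$namespaces), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

## ---- pattern matching ------------------------------------------------------

## Match one pattern against the triple table; returns a data.frame whose
## columns are the pattern's variable names (without "?") and whose rows are
## the satisfying assignments (node keys). A variable-free pattern yields a
## zero-column frame with one row per (deduplicated) hit.
match_one <- function(df, pat) {
  keep <- rep(TRUE, nrow(df))
  for (pos in c("s", "p", "o")) {
    slot <- pat[[pos]]
    if (!is_var(slot)) keep <- keep & (df[[pos]] == slot)
  }
  hit <- df[keep, , drop = FALSE]
  var_pos <- list()  # variable name -> positions it occupies
  for (pos in c("s", "p", "o")) {
    slot <- pat[[pos]]
    if (is_var(slot)) {
      nm <- substring(slot, 2L)
      var_pos[[nm]] <- c(var_pos[[nm]], pos)
    }
  }
  ## a variable repeated within the pattern must bind the same node
  for (nm in names(var_pos)) {
    ps <- var_pos[[nm]]
    if (length(ps) > 1L) {
      for (k in seq_along(ps)[-1L]) {
        hit <- hit[hit[[ps[[1L]]]] == hit[[ps[[k]]]], , drop = FALSE]
      }
    }
  }
  if (length(var_pos) == 0L) {
    return(as.data.frame(matrix(nrow = min(nrow(hit), 1L), ncol = 0L)))
  }
  cols <- lapply(names(var_pos), function(nm) hit[[var_pos[[nm]][[1L]]]])
  out <- stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE), names(var_pos))
  unique(out)
}

join_bindings <- function(a, b) {
  if (is.null(a)) return(b)
  ## zero-column frames act as TRUE (>=1 row) or FALSE (0 rows)
  if (ncol(a) == 0L) return(if (nrow(a) > 0L) b else b[0L, , drop = FALSE])
  if (ncol(b) == 0L) return(if (nrow(b) > 0L) a else a[0L, , drop = FALSE])
  shared <- intersect(names(a), names(b))
  if (length(shared) > 0L) {
    merge(a, b, by = shared, stringsAsFactors = FALSE)
  } else {
    merge(a, b, by = NULL)
  }
}

#' Match a triple pattern against a graph
#'
#' Returns every variable assignment under which the pattern is a triple of
#' the graph. An all-variable pattern enumerates the whole graph; a ground
#' pattern returns a zero-column frame with one row if present, zero if not.
#'
#' @param graph A `kg`.
#' @param pattern A `triple_pattern`.
#' @return Data frame of bindings; one column per variable, values are node keys.
#' @export
kg_match <- function(graph, pattern) {
  stopifnot(is_kg(graph), inherits(pattern, "triple_pattern"))
  out <- match_one(graph$triples, pattern)
  rownames(out) <- NULL
  out
}
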