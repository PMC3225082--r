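#' Default namespace table
#'
#' The graph vocabulary lives in a single project namespace bound to the
#' prefix `wo`, alongside the standard `rdf` and `xsd` namespaces. The `wo`
#' base IRI is an implementation constant.
#'
#' @return Named character vector mapping prefix to base IRI.
#' @export
ce_namespaces <- function() {
  c(
    wo  = "http://chem.example.org/wo#",
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    xsd = "http://www.w3.org/2001/XMLSchema#"
  )
}

#' Construct an IRI term
#'
#' @param value Local name (non-empty string), e.g. `"querycmpd"`.
#' @param prefix Namespace prefix the local name resolves against.
#' @return A `ce_term` of kind `"iri"`.
#' @seealso [literal()], [triple()]
#' @export
iri <- function(value, prefix = "wo") {
  if (!is.character(value) || length(value) != 1L || is.na(value) || !nzchar(value)) {
    stop("IRI term must have a non-empty value", call. = FALSE)
  }
  if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix)) {
    stop("IRI term '", value, "' must carry a namespace prefix", call. = FALSE)
  }
  structure(list(kind = "iri", value = value, prefix = prefix, datatype = NULL),
            class = "ce_term")
}

#' Construct a literal term
#'
#' @param value Literal lexical form (string).
#' @param datatype Optional datatype as a prefixed name, e.g. `"xsd:decimal"`.
#' @return A `ce_term` of kind `"literal"`.
#' @export
literal <- function(value, datatype = NULL) {
  if (length(value) != 1L || is.na(value)) {
    stop("literal term must be a single non-NA value", call. = FALSE)
  }
  structure(list(kind = "literal", value = as.character(value), prefix = NULL,
                 datatype = datatype),
            class = "ce_term")
}

is_term <- function(x) inherits(x, "ce_term")

#' @export
print.ce_term <- function(x, ...) {
  cat(if (x$kind == "iri") term_key(x) else term_key(x), "\n")
  invisible(x)
}

## ---- node keys -------------------------------------------------------------
## Every term has a canonical, injective string key used throughout the
## engine: IRIs are prefixed names ("wo:querycmpd"); literals are N-Triples
## style quoted strings, optionally with a ^^datatype suffix.

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

term_key <- function(t) {
  stopifnot(is_term(t))
  if (t$kind == "iri") {
    paste0(t$prefix, ":", t$value)
  } else {
    k <- paste0("\"", escape_literal(t$value), "\"")
    if (!is.null(t$datatype)) k <- paste0(k, "^^", t$datatype)
    k
  }
}

key_is_literal <- function(key) startsWith(key, "\"")

key_to_term <- function(key) {
  if (key_is_literal(key)) {
    m <- regmatches(key, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(.+))?$', key))[[1]]
    if (length(m) == 0L) stop("malformed literal key: ", key, call. = FALSE)
    dt <- if (nzchar(m[[3]])) m[[3]] else NULL
    literal(unescape_literal(m[[2]]), datatype = dt)
  } else {
    sep <- regexpr(":", key, fixed = TRUE)
    if (sep < 0L) stop("malformed IRI key (no prefix): ", key, call. = FALSE)
    iri(substring(key, sep + 1L), prefix = substring(key, 1L, sep - 1L))
  }
}

## Accept either a ce_term or a prefixed-name string shorthand for IRIs.
as_term <- function(x, what = "term") {
  if (is_term(x)) return(x)
  if (is.character(x) && length(x) == 1L && !is.na(x)) {
    if (startsWith(x, "\"")) return(key_to_term(x))
    sep <- regexpr(":", x, fixed = TRUE)
    if (sep > 0L) return(iri(substring(x, sep + 1L), prefix = substring(x, 1L, sep - 1L)))
  }
  stop("cannot interpret ", what, ": ", deparse(x), call. = FALSE)
}

#' Construct a triple
#'
#' Subject and predicate must be IRIs; the object may be an IRI or a literal.
#' Prefixed-name strings (`"wo:querycmpd"`) are accepted as IRI shorthand.
#'
#' @param s,p,o Subject, predicate and object terms.
#' @return A `ce_triple`.
#' @examples
#' triple("wo:querycmpd", "wo:isSimilarTo", "wo:ctdcid9681")
#' triple("wo:ctdcid9681", "wo:hasSimilarity", literal("1.000"))
#' @export
triple <- function(s, p, o) {
  s <- as_term(s, "subject"); p <- as_term(p, "predicate"); o <- as_term(o, "object")
  if (s$kind != "iri") stop("triple subject must be an IRI term", call. = FALSE)
  if (p$kind != "iri") stop("triple predicate must be an IRI term", call. = FALSE)
  structure(list(s = s, p = p, o = o), class = "ce_triple")
}

#' @export
print.ce_triple <- function(x, ...) {
  cat(term_key(x$s), term_key(x$p), term_key(x$o), ".\n")
  invisible(x)
}

is_var <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && startsWith(x, "?")

## Pattern positions: either a ground node key (string) or a variable "?x".
as_pattern_slot <- function(x, what) {
  if (is_var(x)) return(x)
  term_key(as_term(x, what))
}

#' Construct a triple pattern
#'
#' Each position is a ground term (a `ce_term` or prefixed-name string) or a
#' variable: a string beginning with `"?"`.
#'
#' @param s,p,o Pattern positions.
#' @return A `triple_pattern`.
#' @examples
#' triple_pattern("?c", "rdf:type", "wo:ChemicalCompound")
#' @export
triple_pattern <- function(s, p, o) {
  structure(list(
    s = as_pattern_slot(s, "subject"),
    p = as_pattern_slot(p, "predicate"),
    o = as_pattern_slot(o, "object")
  ), class = "triple_pattern")
}

pattern_vars <- function(pat) {
  slots <- c(pat$s, pat$p, pat$o)
  unique(slots[vapply(slots, is_var, logical(1))])
}

#' @export
print.triple_pattern <- function(x, ...) {
  cat("(", x$s, " ", x$p, " ", x$o, ")\n", sep = "")
  invisible(x)
}
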