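#' Construct an inference rule
#'
#' A rule rewrites matches of its body (a conjunction of triple patterns)
#' into grounded head triples. Rules are range-restricted: every head
#' variable must occur in the body, so inferred triples are always ground.
#' Body predicates must be ground (no predicate variables in rules).
#'
#' @param id Rule identifier, e.g. `"r1"`.
#' @param body List of `triple_pattern` (non-empty).
#' @param head List of `triple_pattern` (typically one).
#' @param provenance `"paper"` for rules printed in the source publication,
#'   `"reconstructed"` for rules this package reconstructs from the described
#'   evidence channels.
#' @return A `ce_rule`.
#' @export
rule <- function(id, body, head, provenance = c("reconstructed", "paper")) {
  provenance <- match.arg(provenance)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("rule id must be a non-empty string", call. = FALSE)
  }
  if (length(body) == 0L) stop("rule '", id, "' has an empty body", call. = FALSE)
  stopifnot(all(vapply(body, inherits, logical(1), "triple_pattern")),
            all(vapply(head, inherits, logical(1), "triple_pattern")))
  for (pat in body) {
    if (is_var(pat$p)) {
      stop("rule '", id, "': body predicates must be ground (got ", pat$p, ")",
           call. = FALSE)
    }
  }
  body_vars <- unique(unlist(lapply(body, pattern_vars)))
  head_vars <- unique(unlist(lapply(head, pattern_vars)))
  unbound <- setdiff(head_vars, body_vars)
  if (length(unbound) > 0L) {
    stop("rule '", id, "' violates range restriction: head variable ",
         paste(unbound, collapse = ", "), " does not occur in the body",
         call. = FALSE)
  }
  structure(list(id = id, body = body, head = head, provenance_tag = provenance),
            class = "ce_rule")
}

#' @export
print.ce_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

format_pattern <- function(pat) paste0("(", pat$s, " ", pat$p, " ", pat$o, ")")

format_rule <- function(r) {
  paste0("[", r$id, ": ",
         paste(vapply(r$body, format_pattern, character(1)), collapse = ", "),
         " -> ",
         paste(vapply(r$head, format_pattern, character(1)), collapse = ", "),
         "]")
}

#' The default rule base
#'
#' Eight compound-to-disease inference rules. `r1`-`r3` are the three rules
#' printed in the source publication, kept verbatim (including Rule 3's
#' unanchored `?CompoundID`, which fires for any compound with bioassay
#' activity -- in practice the graphs contain only the query compound's
#' similar compounds). `r4`-`r8` are reconstructions of the remaining
#' evidence channels, tagged `provenance_tag = "reconstructed"`:
#' \describe{
#'   \item{r4}{direct compound-disease records (CTD channel).}
#'   \item{r5}{query-anchored variant of Rule 3 (bioassay-gene channel).}
#'   \item{r6}{query-anchored literature channel via gene/compound
#'     co-occurrence (`isrelatedTo`).}
#'   \item{r7}{assay-independent target channel (`hasGene` on compounds).}
#'   \item{r8}{article-disease channel via `isContainedIn`.}
#' }
#' Every head is `mightHasDisease`.
#'
#' @return List of 8 `ce_rule` objects.
#' @export
default_rules <- function() {
  P <- triple_pattern
  list(
    rule("r1",
         body = list(P("?QueryCompound", "wo:isSimilarTo", "?CompoundID"),
                     P("?CompoundID", "wo:isActiveIn", "?Bioassay"),
                     P("?Bioassay", "wo:isAssociatedWith", "?Disease")),
         head = list(P("?QueryCompound", "wo:mightHasDisease", "?Disease")),
         provenance = "paper"),
    rule("r2",
         body = list(P("?CompoundID", "wo:isContainedIn", "?Journal"),
                     P("?Journal", "wo:hasGene", "?Gene"),
                     P("?Gene", "wo:isAssociatedWith", "?Disease")),
         head = list(P("?CompoundID", "wo:mightHasDisease", "?Disease")),
         provenance = "paper"),
    rule("r3",
         body = list(P("?CompoundID", "wo:isActiveIn", "?Bioassay"),
                     P("?Bioassay", "wo:hasGene", "?Gene"),
                     P("?Gene", "wo:isAssociatedWith", "?Disease")),
         head = list(P("?CompoundID", "wo:mightHasDisease", "?Disease")),
         provenance = "paper"),
    rule("r4",
         body = list(P("?QueryCompound", "wo:isSimilarTo", "?CompoundID"),
                     P("?CompoundID", "wo:hasDisease", "?Disease")),
         head = list(P("?QueryCompound", "wo:mightHasDisease", "?Disease"))),
    rule("r5",
         body = list(P("?QueryCompound", "wo:isSimilarTo", "?CompoundID"),
                     P("?CompoundID", "wo:isActiveIn", "?Bioassay"),
                     P("?Bioassay", "wo:hasGene", "?Gene"),
                     P("?Gene", "wo:isAssociatedWith", "?Disease")),
         head = list(P("?QueryCompound", "wo:mightHasDisease", "?Disease"))),
    rule("r6",
         body = list(P("?QueryCompound", "wo:isSimilarTo", "?CompoundID"),
                     P("?Gene", "wo:isrelatedTo", "?CompoundID"),
                     P("?Gene", "wo:isAssociatedWith", "?Disease")),
         head = list(P("?QueryCompound", "wo:mightHasDisease", "?Disease"))),
    rule("r7",
         body = list(P("?QueryCompound", "wo:isSimilarTo", "?CompoundID"),
                     P("?CompoundID", "wo:hasGene", "?Gene"),
                     P("?Gene", "wo:isAssociatedWith", "?Disease")),
         head = list(P("?QueryCompound", "wo:mightHasDisease", "?Disease"))),
    rule("r8",
         body = list(P("?QueryCompound", "wo:isSimilarTo", "?CompoundID"),
                     P("?CompoundID", "wo:isContainedIn", "?Journal"),
                     P("?Journal", "wo:hasDisease", "?Disease")),
         head = list(P("?QueryCompound", "wo:mightHasDisease", "?Disease")))
  )
}

## ---- rule DSL ---------------------------------------------------------------
## [id: (pat), (pat), ... -> (pat), ...]
## Pattern positions: ?Var | prefix:Local | "literal". '#' starts a comment.
## Predicate aliases (isSimiliarTo, hasGenes) are canonicalized on parse.

#' Parse rules from the bracketed rule DSL
#'
#' @param text Rule file contents.
#' @param ontology Ontology used to canonicalize predicate aliases.
#' @return List of `ce_rule` (provenance tag `"reconstructed"`; the tag is a
#'   package-level annotation, not part of the DSL).
#' @seealso [write_rules()], [load_rules()]
#' @export
parse_rules <- function(text, ontology = ce_ontology()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ## strip comments outside string literals (rule literals never contain '#')
  lines <- sub("#.*$", "", lines)
  joined <- paste(lines, collapse = "\n")
  rules <- list()
  chars <- strsplit(joined, "", fixed = TRUE)[[1]]
  i <- 1L; line <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch != "[") stop("line ", line, ": expected '[' to open a rule", call. = FALSE)
    depth_line <- line
    j <- i
    while (j <= length(chars) && chars[[j]] != "]") {
      if (chars[[j]] == "\n") line <- line + 1L
      j <- j + 1L
    }
    if (j > length(chars)) stop("line ", depth_line, ": unterminated rule (missing ']')", call. = FALSE)
    rules[[length(rules) + 1L]] <-
      parse_one_rule(paste(chars[(i + 1L):(j - 1L)], collapse = ""), depth_line, ontology)
    i <- j + 1L
  }
  rules
}

parse_one_rule <- function(src, line, ontology) {
  sep <- regexpr(":", src, fixed = TRUE)
  if (sep < 0L) stop("line ", line, ": rule needs an 'id:' prefix", call. = FALSE)
  id <- trimws(substring(src, 1L, sep - 1L))
  rest <- substring(src, sep + 1L)
  arrow <- regexpr("->", rest, fixed = TRUE)
  if (arrow < 0L) stop("line ", line, ": rule '", id, "' has no '->'", call. = FALSE)
  body_src <- substring(rest, 1L, arrow - 1L)
  head_src <- substring(rest, arrow + 2L)
  body <- parse_pattern_list(body_src, line, ontology)
  head <- parse_pattern_list(head_src, line, ontology)
  if (length(body) == 0L) stop("line ", line, ": rule '", id, "' has an empty body", call. = FALSE)
  tryCatch(rule(id, body, head),
           error = function(e) stop("line ", line, ": ", conditionMessage(e), call. = FALSE))
}

parse_pattern_list <- function(src, line, ontology) {
  pats <- list()
  m <- gregexpr("\\(([^()]*)\\)", src)[[1]]
  if (m[[1]] == -1L) return(pats)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    inner <- substring(src, starts[[k]] + 1L, starts[[k]] + lens[[k]] - 2L)
    pats[[k]] <- parse_pattern_terms(inner, line, ontology)
  }
  pats
}

parse_pattern_terms <- function(inner, line, ontology) {
  toks <- regmatches(inner, gregexpr('"[^"]*"|[^ \t\n]+', inner))[[1]]
  if (length(toks) != 3L) {
    stop("line ", line, ": pattern '(", inner, ")' must have 3 positions", call. = FALSE)
  }
  slots <- lapply(seq_along(toks), function(k) {
    tok <- toks[[k]]
    if (startsWith(tok, "?")) return(tok)
    if (startsWith(tok, "\"")) return(literal(substring(tok, 2L, nchar(tok) - 1L)))
    sep <- regexpr(":", tok, fixed = TRUE)
    if (sep < 0L) stop("line ", line, ": expected ?var, prefix:name or \"literal\", got '",
                       tok, "'", call. = FALSE)
    prefix <- substring(tok, 1L, sep - 1L)
    local <- substring(tok, sep + 1L)
    ## the DSL accepts the uppercase WO prefix and known predicate aliases
    if (prefix == "WO") prefix <- "wo"
    if (k == 2L) local <- canonical_predicate(local, ontology)
    iri(local, prefix = prefix)
  })
  triple_pattern(slots[[1]], slots[[2]], slots[[3]])
}

#' Load rules from a file
#' @param file Path to a rule DSL file.
#' @inheritParams parse_rules
#' @return List of `ce_rule`.
#' @export
load_rules <- function(file, ontology = ce_ontology()) {
  parse_rules(paste(readLines(file, warn = FALSE), collapse = "\n"), ontology)
}

#' Serialize rules to the rule DSL
#' @param rules List of `ce_rule`.
#' @param file Optional output path.
#' @return DSL text (invisibly when `file` is given).
#' @export
write_rules <- function(rules, file = NULL) {
  text <- paste0(paste(vapply(rules, format_rule, character(1)), collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}
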