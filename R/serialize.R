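## RDF serialization: N-Triples and Turtle dialects sufficient for the graphs
## this package produces (no blank nodes, no collections, no named graphs).

expand_key <- function(key, namespaces) {
  if (key_is_literal(key)) return(key)
  sep <- regexpr(":", key, fixed = TRUE)
  prefix <- substring(key, 1L, sep - 1L)
  base <- namespaces[[prefix]]
  if (is.null(base)) stop("unknown prefix in '", key, "'", call. = FALSE)
  paste0("<", base, substring(key, sep + 1L), ">")
}

compact_iri <- function(full, namespaces, line = NA) {
  for (prefix in names(namespaces)) {
    base <- namespaces[[prefix]]
    if (startsWith(full, base)) {
      return(paste0(prefix, ":", substring(full, nchar(base) + 1L)))
    }
  }
  stop("line ", line, ": IRI <", full,
       "> does not resolve against any known namespace", call. = FALSE)
}

literal_out <- function(key, namespaces, full_datatype = FALSE) {
  if (!full_datatype) return(key)
  m <- regmatches(key, regexec('^("(?:[^"\\\\]|\\\\.)*")(?:\\^\\^(.+))?$', key))[[1]]
  if (!nzchar(m[[3]])) return(key)
  paste0(m[[2]], "^^", expand_key(m[[3]], namespaces))
}

#' Serialize a graph
#'
#' @param graph A `kg`.
#' @param format `"ntriples"` (full IRIs in angle brackets, one statement per
#'   line) or `"turtle"` (prefixed names, `;` predicate lists grouped by
#'   subject).
#' @param file Optional path; when given the text is written there.
#' @return The document as a single string (invisibly when `file` is given).
#' @export
write_graph <- function(graph, format = c("ntriples", "turtle"), file = NULL) {
  stopifnot(is_kg(graph))
  format <- match.arg(format)
  text <- if (format == "ntriples") write_ntriples_text(graph) else write_turtle_text(graph)
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}

write_ntriples_text <- function(graph) {
  df <- graph$triples
  if (nrow(df) == 0L) return("")
  ns <- graph$namespaces
  s <- vapply(df$s, expand_key, character(1), namespaces = ns)
  p <- vapply(df$p, expand_key, character(1), namespaces = ns)
  o <- vapply(df$o, function(k) {
    if (key_is_literal(k)) literal_out(k, ns, full_datatype = TRUE) else expand_key(k, ns)
  }, character(1))
  paste0(paste(s, p, o, ". "), collapse = "\n") |> paste0("\n")
}

write_turtle_text <- function(graph) {
  ns <- graph$namespaces
  header <- paste0("@prefix ", names(ns), ": <", unname(ns), "> .", collapse = "\n")
  df <- graph$triples
  if (nrow(df) == 0L) return(paste0(header, "\n"))
  out <- c(header, "")
  for (subj in unique(df$s)) {
    rows <- df[df$s == subj, , drop = FALSE]
    po <- paste(rows$p, rows$o)
    body <- paste(po, collapse = " ;\n    ")
    out <- c(out, paste0(subj, " ", body, " ."))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Parse a serialized graph
#'
#' @param text Document text (or a file path for `read_graph_file`).
#' @param format `"ntriples"` or `"turtle"`.
#' @param namespaces Namespace table used to compact full IRIs.
#' @return A `kg`. Parse failures raise an error naming the offending line.
#' @export
read_graph <- function(text, format = c("ntriples", "turtle"),
                       namespaces = ce_namespaces()) {
  format <- match.arg(format)
  if (format == "ntriples") read_ntriples_text(text, namespaces)
  else read_turtle_text(text, namespaces)
}

#' @rdname read_graph
#' @param file Path to a serialized graph.
#' @export
read_graph_file <- function(file, format = c("ntriples", "turtle"),
                            namespaces = ce_namespaces()) {
  read_graph(paste0(paste(readLines(file, warn = FALSE), collapse = "\n"), "\n"),
             format = format, namespaces = namespaces)
}

## ---- tokenizer shared by both readers --------------------------------------
## Token types: iri <...>, literal "..."(^^dt)?, pname prefix:local, punct . ; ,
## and the Turtle keywords @prefix / a.

tokenize_rdf <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L; line <- 1L
  tokens <- list()
  push <- function(type, value, at_line) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, line = at_line)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[[i]] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[[j]] != ">") {
        if (chars[[j]] == "\n") stop("line ", line, ": unterminated IRI", call. = FALSE)
        j <- j + 1L
      }
      if (j > n) stop("line ", line, ": unterminated IRI", call. = FALSE)
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""), line)
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character(0)
      while (j <= n && chars[[j]] != "\"") {
        if (chars[[j]] == "\\" && j < n) { buf <- c(buf, chars[[j]], chars[[j + 1L]]); j <- j + 2L }
        else { if (chars[[j]] == "\n") line <- line + 1L; buf <- c(buf, chars[[j]]); j <- j + 1L }
      }
      if (j > n) stop("line ", line, ": unterminated literal", call. = FALSE)
      lex <- paste(buf, collapse = "")
      i <- j + 1L
      dt <- NULL
      if (i + 1L <= n && chars[[i]] == "^" && chars[[i + 1L]] == "^") {
        i <- i + 2L
        if (i <= n && chars[[i]] == "<") {
          j <- i + 1L
          while (j <= n && chars[[j]] != ">") j <- j + 1L
          if (j > n) stop("line ", line, ": unterminated datatype IRI", call. = FALSE)
          dt <- list(kind = "iri", value = paste(chars[(i + 1L):(j - 1L)], collapse = ""))
          i <- j + 1L
        } else {
          j <- i
          while (j <= n && grepl("[A-Za-z0-9_:.-]", chars[[j]])) j <- j + 1L
          dt <- list(kind = "pname", value = paste(chars[i:(j - 1L)], collapse = ""))
          i <- j
        }
      }
      push("literal", list(lex = lex, datatype = dt), line)
      next
    }
    if (ch %in% c(".", ";", ",")) {
      ## "." inside a pname (e.g. none here) is not produced by our writers
      push("punct", ch, line); i <- i + 1L; next
    }
    ## pname / keyword
    j <- i
    while (j <= n && !(chars[[j]] %in% c(" ", "\t", "\r", "\n", ";", ",", "<", "\"")) &&
           !(chars[[j]] == "." && (j == n || chars[[j + 1L]] %in% c(" ", "\t", "\r", "\n")))) {
      j <- j + 1L
    }
    word <- paste(chars[i:(j - 1L)], collapse = "")
    if (word == "@prefix") push("at_prefix", word, line)
    else if (word == "a") push("kw_a", word, line)
    else push("pname", word, line)
    i <- j
  }
  tokens
}

token_to_key <- function(tok, namespaces) {
  if (tok$type == "iri") return(compact_iri(tok$value, namespaces, tok$line))
  if (tok$type == "pname") {
    sep <- regexpr(":", tok$value, fixed = TRUE)
    if (sep < 0L) stop("line ", tok$line, ": expected a prefixed name, got '",
                       tok$value, "'", call. = FALSE)
    prefix <- substring(tok$value, 1L, sep - 1L)
    if (!(prefix %in% names(namespaces))) {
      stop("line ", tok$line, ": unknown prefix '", prefix, ":'", call. = FALSE)
    }
    return(tok$value)
  }
  if (tok$type == "kw_a") return("rdf:type")
  if (tok$type == "literal") {
    key <- paste0("\"", tok$value$lex, "\"")
    dt <- tok$value$datatype
    if (!is.null(dt)) {
      dtk <- if (dt$kind == "iri") compact_iri(dt$value, namespaces, tok$line) else dt$value
      key <- paste0(key, "^^", dtk)
    }
    return(key)
  }
  stop("line ", tok$line, ": unexpected token '", tok$value, "'", call. = FALSE)
}

read_ntriples_text <- function(text, namespaces = ce_namespaces()) {
  toks <- tokenize_rdf(text)
  g <- kg_new(namespaces)
  rows <- list()
  i <- 1L
  while (i <= length(toks)) {
    if (i + 3L > length(toks)) {
      stop("line ", toks[[i]]$line, ": truncated statement", call. = FALSE)
    }
    s <- token_to_key(toks[[i]], namespaces)
    p <- token_to_key(toks[[i + 1L]], namespaces)
    o <- token_to_key(toks[[i + 2L]], namespaces)
    dot <- toks[[i + 3L]]
    if (!(dot$type == "punct" && dot$value == ".")) {
      stop("line ", dot$line, ": expected '.' after statement", call. = FALSE)
    }
    if (key_is_literal(s) || key_is_literal(p)) {
      stop("line ", toks[[i]]$line, ": subject and predicate must be IRIs", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- c(s, p, o)
    i <- i + 4L
  }
  finish_rows(g, rows)
}

read_turtle_text <- function(text, namespaces = ce_namespaces()) {
  toks <- tokenize_rdf(text)
  ns <- namespaces
  rows <- list()
  i <- 1L
  expect_punct <- function(tok, what) {
    if (!(tok$type == "punct" && tok$value == what)) {
      stop("line ", tok$line, ": expected '", what, "'", call. = FALSE)
    }
  }
  while (i <= length(toks)) {
    if (toks[[i]]$type == "at_prefix") {
      if (i + 3L > length(toks)) stop("line ", toks[[i]]$line, ": truncated @prefix", call. = FALSE)
      pn <- toks[[i + 1L]]
      if (pn$type != "pname" || !endsWith(pn$value, ":")) {
        stop("line ", pn$line, ": malformed @prefix declaration", call. = FALSE)
      }
      base <- toks[[i + 2L]]
      if (base$type != "iri") stop("line ", base$line, ": @prefix needs an IRI", call. = FALSE)
      expect_punct(toks[[i + 3L]], ".")
      ns[[sub(":$", "", pn$value)]] <- base$value
      i <- i + 4L
      next
    }
    subj <- token_to_key(toks[[i]], ns)
    if (key_is_literal(subj)) stop("line ", toks[[i]]$line, ": literal subject", call. = FALSE)
    i <- i + 1L
    repeat {
      if (i + 1L > length(toks)) stop("truncated statement at end of document", call. = FALSE)
      pred <- token_to_key(toks[[i]], ns)
      if (key_is_literal(pred)) stop("line ", toks[[i]]$line, ": literal predicate", call. = FALSE)
      i <- i + 1L
      repeat {
        obj <- token_to_key(toks[[i]], ns)
        rows[[length(rows) + 1L]] <- c(subj, pred, obj)
        i <- i + 1L
        if (i > length(toks)) stop("missing terminating '.'", call. = FALSE)
        tok <- toks[[i]]
        if (tok$type == "punct" && tok$value == ",") { i <- i + 1L; next }
        break
      }
      tok <- toks[[i]]
      if (tok$type == "punct" && tok$value == ";") { i <- i + 1L; next }
      expect_punct(tok, ".")
      i <- i + 1L
      break
    }
  }
  finish_rows(kg_new(ns), rows)
}

finish_rows <- function(g, rows) {
  if (length(rows) == 0L) return(g)
  m <- do.call(rbind, rows)
  kg_add_rows(g, data.frame(s = m[, 1], p = m[, 2], o = m[, 3], stringsAsFactors = FALSE))
}
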