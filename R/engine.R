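#' Match a rule body against a graph
#'
#' Computes the conjunctive join of the body patterns: every total assignment
#' of the body's variables under which all patterns are simultaneously triples
#' of the graph. The result is independent of body pattern order.
#'
#' @param graph A `kg`.
#' @param body List of `triple_pattern`.
#' @return Data frame of bindings, one column per body variable (node keys).
#' @export
match_body <- function(graph, body) {
  stopifnot(is_kg(graph), length(body) > 0L)
  acc <- NULL
  for (pat in body) {
    m <- match_one(graph$triples, pat)
    acc <- join_bindings(acc, m)
    if (nrow(acc) == 0L) break
  }
  acc <- unique(acc)
  rownames(acc) <- NULL
  acc
}

## Substitute one binding row into a pattern -> node-key row
ground_pattern <- function(pat, binding_row) {
  slot <- function(x) {
    if (is_var(x)) as.character(binding_row[[substring(x, 2L)]]) else x
  }
  c(s = slot(pat$s), p = slot(pat$p), o = slot(pat$o))
}

binding_signature <- function(binding_row, vars) {
  paste(vapply(sort(vars), function(v) paste0(v, "=", binding_row[[v]]), character(1)),
        collapse = "|")
}

new_evidence_path <- function(r, binding_row) {
  vars <- unique(unlist(lapply(r$body, pattern_vars)))
  vars <- substring(vars, 2L)
  gb <- do.call(rbind, lapply(r$body, ground_pattern, binding_row = binding_row))
  gh <- do.call(rbind, lapply(r$head, ground_pattern, binding_row = binding_row))
  structure(list(
    rule_id = r$id,
    provenance_tag = r$provenance_tag,
    binding = stats::setNames(
      vapply(vars, function(v) as.character(binding_row[[v]]), character(1)), vars),
    grounded_body = data.frame(s = gb[, "s"], p = gb[, "p"], o = gb[, "o"],
                               stringsAsFactors = FALSE),
    inferred = data.frame(s = gh[, "s"], p = gh[, "p"], o = gh[, "o"],
                          stringsAsFactors = FALSE)
  ), class = "evidence_path")
}

path_identity <- function(p) {
  paste0(p$rule_id, "::",
         paste(names(p$binding), p$binding, sep = "=", collapse = "|"))
}

#' @export
print.evidence_path <- function(x, ...) {
  cat("<evidence path ", x$rule_id, ": ",
      paste(names(x$binding), x$binding, sep = "=", collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Forward-chain a rule base to fixpoint
#'
#' Naive fixpoint iteration: all rules are re-evaluated against the current
#' graph and every firing is recorded as an evidence path, until an iteration
#' adds no triple and no path. The result is independent of rule order and of
#' body-pattern order. Two firings with different body-variable bindings are
#' distinct evidence paths even when they infer the same head triple.
#'
#' @param graph A `kg`.
#' @param rules List of `ce_rule`.
#' @param max_iterations Safety cap on fixpoint iterations; the default rule
#'   base converges in two (its head vocabulary feeds no body), but the cap
#'   guards user-supplied recursive rule sets.
#' @return An `inference_result`: list with `graph` (input plus inferred
#'   triples), `paths` (list of `evidence_path`), `input` (the input graph)
#'   and `inferred` (data frame of the newly derived triples).
#' @export
forward_chain <- function(graph, rules, max_iterations = 100L) {
  stopifnot(is_kg(graph))
  g <- graph
  paths <- list()
  seen <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iterations) {
      stop("forward chaining did not reach a fixpoint within ", max_iterations,
           " iterations; the rule set may be recursive beyond the cap", call. = FALSE)
    }
    changed <- FALSE
    for (r in rules) {
      b <- match_body(g, r$body)
      if (nrow(b) == 0L) next
      for (row_i in seq_len(nrow(b))) {
        p <- new_evidence_path(r, b[row_i, , drop = FALSE])
        pid <- path_identity(p)
        if (pid %in% seen) next
        seen <- c(seen, pid)
        paths[[length(paths) + 1L]] <- p
        g <- kg_add_rows(g, p$inferred)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  inferred <- g$triples[!(triple_keys(g$triples) %in% triple_keys(graph$triples)), ,
                        drop = FALSE]
  rownames(inferred) <- NULL
  structure(list(graph = g, paths = paths, input = graph, inferred = inferred),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference result: ", kg_size(x$input), " input triples, ",
      nrow(x$inferred), " inferred, ", length(x$paths), " evidence paths>\n", sep = "")
  invisible(x)
}

## ---- evidence path JSON interchange ----------------------------------------

#' Write evidence paths to JSON
#'
#' Interchange format used between pipeline stages: the node-type map of the
#' materialized graph plus one record per path (rule, provenance tag, binding,
#' grounded body, inferred triples).
#'
#' @param result An `inference_result`.
#' @param file Optional output path.
#' @return JSON text (invisibly when `file` is given).
#' @export
write_paths_json <- function(result, file = NULL) {
  stopifnot(inherits(result, "inference_result"))
  types <- node_types(result$graph)
  doc <- list(
    node_types = as.list(types),
    paths = lapply(result$paths, function(p) {
      list(rule = p$rule_id,
           provenance_tag = p$provenance_tag,
           binding = as.list(p$binding),
           grounded_body = unname(apply(p$grounded_body, 1L, as.list)),
           inferred = unname(apply(p$inferred, 1L, as.list)))
    })
  )
  text <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

#' Read evidence paths from JSON
#'
#' @param file Path (or JSON text) produced by [write_paths_json()].
#' @return A `path_set`: list with `paths` and `node_types`, sufficient for
#'   clustering, ranking and faceted filtering without the full graph.
#' @export
read_paths_json <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  paths <- lapply(doc$paths, function(p) {
    gb <- do.call(rbind, lapply(p$grounded_body, function(t) unlist(t[c("s", "p", "o")])))
    gh <- do.call(rbind, lapply(p$inferred, function(t) unlist(t[c("s", "p", "o")])))
    structure(list(
      rule_id = p$rule,
      provenance_tag = p$provenance_tag,
      binding = unlist(p$binding),
      grounded_body = data.frame(s = gb[, "s"], p = gb[, "p"], o = gb[, "o"],
                                 stringsAsFactors = FALSE),
      inferred = data.frame(s = gh[, "s"], p = gh[, "p"], o = gh[, "o"],
                            stringsAsFactors = FALSE)
    ), class = "evidence_path")
  })
  structure(list(paths = paths, node_types = unlist(doc$node_types)),
            class = "path_set")
}
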