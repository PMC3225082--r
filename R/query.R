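## Stepwise construction of conjunctive graph-pattern queries.

#' Create an empty query specification
#'
#' A query spec is an ordered list of steps, each constraining a class-typed
#' subject by a property and an object (another class, a literal, or a
#' literal-contains filter). Occurrences of the same class across steps bind
#' to the same variable.
#'
#' @param ontology Ontology against which steps are checked.
#' @return A `query_spec` with zero steps.
#' @export
query_spec <- function(ontology = ce_ontology()) {
  structure(list(steps = list(), ontology = ontology), class = "query_spec")
}

#' Object constraints for query steps
#'
#' @param class Ontology class name, e.g. `"JournalArticle"`.
#' @param value Literal value.
#' @param needle Substring a literal object must contain.
#' @param ignore_case Case-insensitive containment (default FALSE: the
#'   canonical behaviour is case-sensitive, so a query for "5-HT" does not
#'   match "5-ht").
#' @return An object-constraint marker consumed by [add_step()].
#' @name object_constraints
NULL

#' @rdname object_constraints
#' @export
obj_class <- function(class) structure(list(class = class), class = "qb_class")

#' @rdname object_constraints
#' @export
obj_literal <- function(value) structure(list(value = as.character(value)), class = "qb_literal")

#' @rdname object_constraints
#' @export
obj_contains <- function(needle, ignore_case = FALSE) {
  structure(list(needle = as.character(needle), ignore_case = isTRUE(ignore_case)),
            class = "qb_contains")
}

#' Append a step to a query spec
#'
#' @param spec A `query_spec`.
#' @param subject_class Class of the step's subject.
#' @param property Declared property name (local name, e.g. `"isContainedIn"`).
#' @param object One of [obj_class()], [obj_literal()], [obj_contains()], or a
#'   bare string naming a class.
#' @return The spec grown by one step.
#' @export
add_step <- function(spec, subject_class, property, object) {
  stopifnot(inherits(spec, "query_spec"))
  ont <- spec$ontology
  if (is.character(object) && length(object) == 1L) object <- obj_class(object)
  if (!(subject_class %in% ont$classes)) {
    stop("unknown subject class '", subject_class, "'", call. = FALSE)
  }
  property <- canonical_predicate(property, ont)
  if (!(property %in% names(ont$properties))) {
    stop("undeclared property '", property, "'", call. = FALSE)
  }
  if (inherits(object, "qb_class") && !(object$class %in% ont$classes)) {
    stop("unknown object class '", object$class, "'", call. = FALSE)
  }
  if (!inherits(object, c("qb_class", "qb_literal", "qb_contains"))) {
    stop("object must be obj_class(), obj_literal() or obj_contains()", call. = FALSE)
  }
  spec$steps[[length(spec$steps) + 1L]] <-
    list(subject_class = subject_class, property = property, object = object)
  spec
}

#' @export
print.query_spec <- function(x, ...) {
  cat("<query spec: ", length(x$steps), " steps>\n", sep = "")
  for (st in x$steps) {
    obj <- st$object
    objs <- if (inherits(obj, "qb_class")) obj$class
            else if (inherits(obj, "qb_literal")) paste0("\"", obj$value, "\"")
            else paste0("contains(\"", obj$needle, "\")")
    cat("  ", st$subject_class, " ", st$property, " ", objs, "\n", sep = "")
  }
  invisible(x)
}

## Deterministic class variables: lowercase initial + index by first appearance.
class_variables <- function(steps) {
  classes <- character(0)
  for (st in steps) {
    classes <- c(classes, st$subject_class)
    if (inherits(st$object, "qb_class")) classes <- c(classes, st$object$class)
  }
  classes <- unique(classes)
  vars <- character(length(classes))
  used <- character(0)
  for (i in seq_along(classes)) {
    base <- tolower(substring(classes[[i]], 1L, 1L))
    k <- 1L
    while (paste0(base, k) %in% used) k <- k + 1L
    vars[[i]] <- paste0(base, k)
    used <- c(used, vars[[i]])
  }
  stats::setNames(paste0("?", vars), classes)
}

#' Compile a query spec to a conjunctive pattern
#'
#' Emits one `rdf:type` pattern per distinct class variable plus one pattern
#' per step; `obj_contains` constraints become literal variables (`?t1`, ...)
#' with substring filters.
#'
#' @param spec A `query_spec` with at least one step.
#' @return List with `patterns` (list of `triple_pattern`) and `filters`
#'   (list of `(var, needle, ignore_case)`).
#' @export
compile_query <- function(spec) {
  stopifnot(inherits(spec, "query_spec"))
  if (length(spec$steps) == 0L) stop("query spec has no steps", call. = FALSE)
  cvars <- class_variables(spec$steps)
  patterns <- lapply(names(cvars), function(cls) {
    triple_pattern(cvars[[cls]], "rdf:type", paste0("wo:", cls))
  })
  filters <- list()
  t_index <- 0L
  for (st in spec$steps) {
    svar <- cvars[[st$subject_class]]
    pred <- paste0("wo:", st$property)
    obj <- st$object
    if (inherits(obj, "qb_class")) {
      patterns[[length(patterns) + 1L]] <- triple_pattern(svar, pred, cvars[[obj$class]])
    } else if (inherits(obj, "qb_literal")) {
      patterns[[length(patterns) + 1L]] <- triple_pattern(svar, pred, literal(obj$value))
    } else {
      t_index <- t_index + 1L
      tvar <- paste0("?t", t_index)
      patterns[[length(patterns) + 1L]] <- triple_pattern(svar, pred, tvar)
      filters[[length(filters) + 1L]] <-
        list(var = substring(tvar, 2L), needle = obj$needle, ignore_case = obj$ignore_case)
    }
  }
  list(patterns = patterns, filters = filters)
}

#' Execute a query spec against a graph
#'
#' Joins the compiled patterns ([match_body()]), applies the literal-contains
#' filters, removes duplicate rows and sorts deterministically by binding
#' values.
#'
#' @param spec A `query_spec`.
#' @param graph A `kg`.
#' @return Data frame of distinct bindings (node keys), one column per
#'   variable, ordered.
#' @export
execute_query <- function(spec, graph) {
  compiled <- compile_query(spec)
  b <- match_body(graph, compiled$patterns)
  for (f in compiled$filters) {
    if (nrow(b) == 0L) break
    vals <- vapply(b[[f$var]], literal_value, character(1))
    hit <- if (f$ignore_case) {
      grepl(tolower(f$needle), tolower(vals), fixed = TRUE)
    } else {
      grepl(f$needle, vals, fixed = TRUE)
    }
    b <- b[hit, , drop = FALSE]
  }
  b <- unique(b)
  if (nrow(b) > 1L) {
    b <- b[do.call(order, c(unname(as.list(b)), list(method = "radix"))), , drop = FALSE]
  }
  rownames(b) <- NULL
  b
}

#' Read a query spec from YAML
#'
#' Step list schema: each entry has `subject`, `property` and an `object`
#' that is either `{class: X}`, `{literal: v}` or `{contains: s}` (optionally
#' with `ignore_case: true`).
#'
#' @param file YAML path (or YAML text).
#' @param ontology Ontology for validation.
#' @return A `query_spec`.
#' @export
read_query_yaml <- function(file, ontology = ce_ontology()) {
  doc <- if (file.exists(file)) yaml::read_yaml(file) else yaml::yaml.load(file)
  if (is.null(doc$steps)) stop("query YAML must have a 'steps' list", call. = FALSE)
  spec <- query_spec(ontology)
  for (st in doc$steps) {
    obj <- st$object
    constraint <-
      if (!is.null(obj$class)) obj_class(obj$class)
      else if (!is.null(obj$literal)) obj_literal(obj$literal)
      else if (!is.null(obj$contains)) obj_contains(obj$contains, isTRUE(obj$ignore_case))
      else stop("step object must be one of class:/literal:/contains:", call. = FALSE)
    spec <- add_step(spec, st$subject, st$property, constraint)
  }
  spec
}
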