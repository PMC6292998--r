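# Existential path queries over the knowledge base, plus availability tables.
#
# A query is a start type and a condition tree; an instance is returned iff
# the condition holds, with RELATED interpreted existentially (there exists
# a relation of that label whose other endpoint satisfies the nested
# condition).

cond <- function(kind, ...) structure(list(kind = kind, ...),
                                      class = "ckb_cond")

#' Query condition constructors
#'
#' Build the condition tree of a \code{\link{ckb_query}}:
#' \describe{
#'   \item{q_related(label, nested)}{there exists a relation traversable by
#'     \code{label} (a forward or backward relation label) from the
#'     candidate whose other endpoint satisfies \code{nested} (or any
#'     endpoint when \code{nested} is NULL).}
#'   \item{q_in_context(id)}{the candidate is a member of a context instance
#'     with that identifier.}
#'   \item{q_has_entry(method, attr, cmp, value)}{some data entry of the
#'     method keyed by the candidate satisfies the comparison; \code{cmp}
#'     one of <, <=, =, >=, >, !=.}
#'   \item{q_ontology_within(ontology, root, include_self)}{the candidate is
#'     a term of the ontology lying in the is-a transitive closure of
#'     \code{root} — the engine's only built-in inference.}
#'   \item{q_label_is(text)}{case-insensitive match on any free-text label.}
#'   \item{q_id_is(text)}{exact, case-sensitive identifier match.}
#'   \item{q_type_is(type)}{the candidate's object type (or relation class)
#'     name equals \code{type}.}
#'   \item{q_has_annotation(schema, attr, cmp, value)}{some annotation under
#'     the schema satisfies the comparison.}
#'   \item{q_and(...), q_or(...), q_not(x)}{standard logic over child
#'     conditions.}
#' }
#'
#' @param label,id,text,type,schema,method,attr,cmp,value,ontology,root,include_self
#'   see the list above.
#' @param nested a condition or NULL (match any endpoint).
#' @param ...,x child conditions.
#' @return A condition object of class \code{ckb_cond}.
#' @name conditions
NULL

#' @rdname conditions
#' @export
q_related <- function(label, nested = NULL) cond("RELATED", label = label,
                                                 nested = nested)
#' @rdname conditions
#' @export
q_in_context <- function(id) cond("IN_CONTEXT", id = id)
#' @rdname conditions
#' @export
q_has_entry <- function(method, attr, cmp, value)
  cond("HAS_ENTRY", method = method, attr = attr, cmp = cmp, value = value)
#' @rdname conditions
#' @export
q_ontology_within <- function(ontology, root, include_self = TRUE)
  cond("ONTOLOGY_WITHIN", ontology = ontology, root = root,
       include_self = include_self)
#' @rdname conditions
#' @export
q_label_is <- function(text) cond("LABEL_IS", text = text)
#' @rdname conditions
#' @export
q_id_is <- function(id) cond("ID_IS", id = id)
#' @rdname conditions
#' @export
q_type_is <- function(type) cond("TYPE_IS", type = type)
#' @rdname conditions
#' @export
q_has_annotation <- function(schema, attr, cmp, value)
  cond("HAS_ANNOTATION", schema = schema, attr = attr, cmp = cmp,
       value = value)
#' @rdname conditions
#' @export
q_and <- function(...) cond("AND", children = list(...))
#' @rdname conditions
#' @export
q_or <- function(...) cond("OR", children = list(...))
#' @rdname conditions
#' @export
q_not <- function(x) cond("NOT", children = list(x))

#' Construct a query
#'
#' @param start_type the object type of candidate instances.
#' @param condition a condition tree (see \code{\link{conditions}}), or NULL
#'   to return all instances of the type.
#' @return An object of class \code{ckb_query}.
#' @export
ckb_query <- function(start_type, condition = NULL) {
  structure(list(start_type = start_type, condition = condition),
            class = "ckb_query")
}

apply_cmp <- function(cmp, a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    return(switch(cmp, "=" = , "==" = identical(as.character(a), as.character(b)),
                  "!=" = !identical(as.character(a), as.character(b)),
                  ckb_stop("comparators <, <=, >=, > apply to numeric attributes only",
                           "ckb_query_error")))
  switch(cmp,
         "<" = a < b, "<=" = a <= b, "=" = , "==" = a == b,
         ">=" = a >= b, ">" = a > b, "!=" = a != b,
         ckb_stop(sprintf("unknown comparator '%s'", cmp), "ckb_query_error"))
}

# validate that every name in the condition resolves (errors, not empty results)
check_condition <- function(kb, condition) {
  if (is.null(condition)) return(invisible(TRUE))
  switch(condition$kind,
    RELATED = {
      kb_resolve_label(kb, condition$label)
      check_condition(kb, condition$nested)
    },
    HAS_ENTRY = kb_method(kb, condition$method),
    ONTOLOGY_WITHIN = {
      o <- kb$ontologies[[condition$ontology]]
      if (is.null(o))
        ckb_stop(sprintf("unknown ontology '%s'", condition$ontology),
                 "ckb_query_error")
      if (!condition$root %in% names(o$children))
        ckb_stop(sprintf("unknown ontology term '%s'", condition$root),
                 "ckb_query_error")
    },
    TYPE_IS = {
      if (is.null(kb$types[[condition$type]]) &&
          is.null(kb$classes[[condition$type]]))
        ckb_stop(sprintf("unknown type '%s' in condition", condition$type),
                 "ckb_query_error")
    },
    HAS_ANNOTATION = {
      if (is.null(kb$schemas[[condition$schema]]))
        ckb_stop(sprintf("unknown annotation schema '%s'", condition$schema),
                 "ckb_query_error")
    },
    AND = , OR = , NOT = {
      for (ch in condition$children) check_condition(kb, ch)
    },
    IN_CONTEXT = , LABEL_IS = , ID_IS = NULL)
  invisible(TRUE)
}

eval_condition <- function(kb, ref, condition) {
  if (is.null(condition)) return(TRUE)
  switch(condition$kind,
    RELATED = {
      others <- kb_neighbors(kb, ref, condition$label)
      for (o in others) {
        if (eval_condition(kb, o, condition$nested)) return(TRUE)
      }
      FALSE
    },
    IN_CONTEXT = {
      for (ctx in ls(kb$contexts)) {
        if (ref_id(ctx) == condition$id &&
            ref %in% kb$contexts[[ctx]]) return(TRUE)
      }
      FALSE
    },
    HAS_ENTRY = {
      keys <- kb$entries_by_msub[[paste(condition$method, ref, sep = .SEP)]]
      if (is.null(keys)) return(FALSE)
      for (key in keys) {
        v <- kb$entries[[key]]$values[[condition$attr]]
        if (!is.null(v) && isTRUE(apply_cmp(condition$cmp, v, condition$value)))
          return(TRUE)
      }
      FALSE
    },
    ONTOLOGY_WITHIN = {
      if (is_rel_ref(ref)) return(FALSE)
      rec <- kb$instances[[ref]]
      if (rec$type != condition$ontology) return(FALSE)
      rec$id %in% ontology_descendants(kb, condition$ontology, condition$root,
                                       include_self = condition$include_self)
    },
    LABEL_IS = {
      if (is_rel_ref(ref)) return(FALSE)
      tolower(condition$text) %in% tolower(kb$instances[[ref]]$labels)
    },
    ID_IS = !is_rel_ref(ref) && kb$instances[[ref]]$id == condition$id,
    TYPE_IS = ref_type(kb, ref) == condition$type,
    HAS_ANNOTATION = {
      anns <- kb_annotations(kb, ref, condition$schema)
      for (a in anns) {
        v <- a$values[[condition$attr]]
        if (!is.null(v) && isTRUE(apply_cmp(condition$cmp, v, condition$value)))
          return(TRUE)
      }
      FALSE
    },
    AND = {
      for (ch in condition$children)
        if (!eval_condition(kb, ref, ch)) return(FALSE)
      TRUE
    },
    OR = {
      if (!length(condition$children)) return(FALSE)
      for (ch in condition$children)
        if (eval_condition(kb, ref, ch)) return(TRUE)
      FALSE
    },
    NOT = !eval_condition(kb, ref, condition$children[[1]]),
    ckb_stop(sprintf("unknown condition kind '%s'", condition$kind),
             "ckb_query_error"))
}

#' Evaluate a query
#'
#' Returns every instance of the start type that satisfies the condition
#' tree under existential semantics, deduplicated and sorted by
#' (type, identifier) for reproducibility. Unresolvable type, label, method
#' or ontology names raise a query error rather than returning an empty
#' result.
#'
#' @param kb a knowledge base.
#' @param query a \code{\link{ckb_query}}.
#' @return data.frame with columns \code{type}, \code{identifier},
#'   \code{ref}.
#' @export
kb_evaluate <- function(kb, query) {
  kb_type(kb, query$start_type)
  check_condition(kb, query$condition)
  refs <- kb_instances(kb, query$start_type)
  hits <- refs[vapply(refs, function(r) isTRUE(eval_condition(kb, r, query$condition)),
                      TRUE)]
  hits <- unique(hits)
  ids <- vapply(hits, ref_id, "")
  ord <- order(ids, method = "radix")
  data.frame(type = rep(query$start_type, length(hits)),
             identifier = ids[ord],
             ref = hits[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- availability tables ---------------------------------------------------

#' Availability-table column specifications
#'
#' \code{col_path} follows a sequence of relation labels from each result
#' instance and places the endpoint identifier (or first label) in the cell;
#' \code{col_entry} places a stored measurement value of the result instance
#' itself.
#'
#' @param ... relation labels forming the path.
#' @param cell "identifier" or "label".
#' @param method,attr,format_name entry lookup, as in
#'   \code{\link{kb_entry_value}}.
#' @return A column specification.
#' @export
col_path <- function(..., cell = c("identifier", "label")) {
  structure(list(type = "path", labels = c(...), cell = match.arg(cell)),
            class = "ckb_col")
}

#' @rdname col_path
#' @export
col_entry <- function(method, attr = NULL, format_name = NULL) {
  structure(list(type = "entry", method = method, attr = attr,
                 format_name = format_name), class = "ckb_col")
}

path_endpoints <- function(kb, ref, labels) {
  frontier <- ref
  for (lab in labels) {
    nxt <- character()
    for (f in frontier) nxt <- c(nxt, kb_neighbors(kb, f, lab))
    frontier <- unique(nxt)
    if (!length(frontier)) return(character())
  }
  sort(frontier, method = "radix")
}

cell_of <- function(kb, ref, cellkind) {
  if (is_rel_ref(ref)) {
    rec <- kb$relations[[ref]]
    return(paste0(ref_id(rec$source), "->", ref_id(rec$target)))
  }
  rec <- kb$instances[[ref]]
  if (cellkind == "label" && length(rec$labels)) rec$labels[1] else rec$id
}

#' Expand query results into an availability table
#'
#' One row per binding of (result instance, path endpoints): for each result
#' instance the endpoint sets of all path columns are crossed; a path with
#' no match contributes a single empty (NA) cell so the instance still
#' appears. Entry columns carry measurement values of the result instance.
#'
#' @param kb a knowledge base.
#' @param query a \code{\link{ckb_query}}.
#' @param columns named list of \code{\link{col_path}} /
#'   \code{\link{col_entry}} specifications; when empty, the table has the
#'   single column \code{identifier}.
#' @return A data.frame; first column \code{identifier} of the result
#'   instance.
#' @export
kb_availability_table <- function(kb, query, columns = list()) {
  res <- kb_evaluate(kb, query)
  for (cl in columns) {
    if (!inherits(cl, "ckb_col"))
      ckb_stop("columns must be col_path()/col_entry() specifications",
               "ckb_query_error")
    if (cl$type == "path")
      for (lab in cl$labels) kb_resolve_label(kb, lab)
    else kb_method(kb, cl$method)
  }
  if (!length(columns))
    return(data.frame(identifier = res$identifier, stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(res))) {
    ref <- res$ref[i]
    per_col <- lapply(columns, function(cl) {
      if (cl$type == "path") {
        eps <- path_endpoints(kb, ref, cl$labels)
        if (!length(eps)) NA_character_
        else vapply(eps, function(e) cell_of(kb, e, cl$cell), "")
      } else {
        as.character(kb_entry_value(kb, cl$method, ref, cl$attr,
                                    cl$format_name))
      }
    })
    grid <- expand.grid(rev(per_col), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(per_col)), drop = FALSE]
    names(grid) <- names(columns)
    rows[[i]] <- cbind(data.frame(identifier = res$identifier[i],
                                  stringsAsFactors = FALSE), grid,
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(data.frame(identifier = character(), stringsAsFactors = FALSE),
                 stats::setNames(replicate(length(columns),
                                           character(), simplify = FALSE),
                                 names(columns)))
  out
}

# ---- JSON query syntax -----------------------------------------------------

cond_to_list <- function(condition) {
  if (is.null(condition)) return(NULL)
  out <- unclass(condition)
  if (!is.null(out$nested)) out$nested <- cond_to_list(out$nested)
  if (!is.null(out$children)) out$children <- lapply(out$children, cond_to_list)
  out
}

cond_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  x <- as.list(x)
  if (!is.null(x$nested)) x$nested <- cond_from_list(x$nested)
  if (!is.null(x$children)) x$children <- lapply(x$children, cond_from_list)
  structure(x, class = "ckb_cond")
}

#' Serialize / parse queries as JSON
#'
#' The JSON form mirrors the condition tree: each node is an object with a
#' \code{kind} field (RELATED, IN_CONTEXT, HAS_ENTRY, ONTOLOGY_WITHIN,
#' LABEL_IS, ID_IS, TYPE_IS, HAS_ANNOTATION, AND, OR, NOT) and that kind's
#' parameters; the query wraps \code{start_type} and \code{condition}.
#'
#' @param query a \code{\link{ckb_query}}.
#' @param txt JSON text or a file path.
#' @return \code{query_to_json} returns a JSON string; \code{query_from_json}
#'   a \code{ckb_query}.
#' @export
query_to_json <- function(query) {
  jsonlite::toJSON(list(start_type = query$start_type,
                        condition = cond_to_list(query$condition)),
                   auto_unbox = TRUE, null = "null")
}

#' @rdname query_to_json
#' @export
query_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  ckb_query(x$start_type, cond_from_list(x$condition))
}
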