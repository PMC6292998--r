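# Core semantic-network substrate: object kinds, dynamic object types,
# instances, relation classes, relation instances, annotations, contexts.

#' Static semantic object kinds
#'
#' The closed set of object kinds from which dynamic object types are derived:
#' \code{ELEMENT} (plain domain objects such as patients or brain coordinates),
#' \code{CONTEXT} (grouping objects such as studies or brain structures),
#' \code{EXPERIMENT} (subject-indexed measurement stores), \code{ONTOLOGY}
#' (hierarchies with is-a edges) and \code{ANNOTATION} (meta-information).
#'
#' @format A character vector of the five kind names.
#' @export
OBJECT_KINDS <- c("ELEMENT", "CONTEXT", "EXPERIMENT", "ONTOLOGY", "ANNOTATION")

# internal ref encoding: instances "type\x1fid"; relations "\x02<counter>"
.SEP <- "\x1f"

ckb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ckb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Build an instance reference
#'
#' Instances are addressed by an opaque reference string combining type name
#' and identifier. References are the currency passed between knowledge-base
#' operations.
#'
#' @param type object type name.
#' @param id instance identifier (case-sensitive, unique within the type).
#' @return A reference string.
#' @export
ckb_ref <- function(type, id) paste0(type, .SEP, id)

is_rel_ref <- function(ref) startsWith(ref, "\x02")

ref_type <- function(kb, ref) {
  if (is_rel_ref(ref)) kb$relations[[ref]]$class
  else sub(paste0(.SEP, ".*$"), "", ref)
}

ref_id <- function(ref) sub(paste0("^.*?", .SEP), "", ref)

#' Create an empty knowledge base
#'
#' The knowledge base is the registry of object types, relation classes,
#' annotation schemas, instances, relation instances, context memberships,
#' experiment methods, experiments, data entries and ontologies. It is a
#' mutable environment: all \code{kb_*} operations modify it in place and
#' return the created object (or its reference) invisibly.
#'
#' @param brain_model if \code{TRUE}, pre-install the standard brain-science
#'   model (see \code{\link{kb_brain_model}}).
#' @return An object of class \code{kb}.
#' @examples
#' kb <- kb_new()
#' kb_define_object_type(kb, "patient", "ELEMENT")
#' kb_create_instance(kb, "patient", "P1")
#' @export
kb_new <- function(brain_model = FALSE) {
  kb <- new.env(parent = emptyenv())
  kb$types <- list()            # name -> list(name, kind, schemas)
  kb$classes <- list()          # name -> list(name, forward, backward, pairs, schemas)
  kb$labels <- list()           # lowercase traversal label -> list(class, direction)
  kb$schemas <- list()          # name -> list(name, attributes)
  kb$instances <- new.env(parent = emptyenv())   # ref -> instance record
  kb$inst_by_type <- new.env(parent = emptyenv())# type -> character refs
  kb$relations <- new.env(parent = emptyenv())   # rel ref -> relation record
  kb$rel_lookup <- new.env(parent = emptyenv())  # class\x1fsrc\x1ftgt -> rel ref
  kb$rel_by_source <- new.env(parent = emptyenv())
  kb$rel_by_target <- new.env(parent = emptyenv())
  kb$rel_by_class <- new.env(parent = emptyenv())
  kb$rel_counter <- 0L
  kb$contexts <- new.env(parent = emptyenv())    # context ref -> member refs
  kb$methods <- list()          # experiment methods
  kb$experiments <- new.env(parent = emptyenv()) # method\x1fname -> record
  kb$entries <- new.env(parent = emptyenv())     # method\x1fexp\x1fsubj\x1ffmt -> record
  kb$entries_by_msub <- new.env(parent = emptyenv()) # method\x1fsubj -> entry keys
  kb$ontologies <- list()       # name -> list(parents, children, roots)
  class(kb) <- "kb"
  if (brain_model) kb_brain_model(kb)
  kb
}

#' @export
print.kb <- function(x, ...) {
  cat(sprintf(
    "<knowledge base: %d types, %d relation classes, %d instances, %d relations, %d methods>\n",
    length(x$types), length(x$classes), length(ls(x$instances)),
    length(ls(x$relations)), length(x$methods)))
  invisible(x)
}

#' Define a dynamic object type
#'
#' Derives a new object type from one of the five static object kinds.
#'
#' @param kb a knowledge base.
#' @param name unique type name.
#' @param kind one of \code{\link{OBJECT_KINDS}}.
#' @return The type definition, invisibly.
#' @export
kb_define_object_type <- function(kb, name, kind) {
  kind <- match.arg(kind, OBJECT_KINDS)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    ckb_stop("type name must be a non-empty string", "ckb_definition_error")
  if (!is.null(kb$types[[name]]))
    ckb_stop(sprintf("object type '%s' is already defined", name),
             "ckb_definition_error")
  def <- list(name = name, kind = kind, schemas = character())
  kb$types[[name]] <- def
  invisible(def)
}

kb_type <- function(kb, name) {
  t <- kb$types[[name]]
  if (is.null(t))
    ckb_stop(sprintf("unknown object type '%s'", name), "ckb_definition_error")
  t
}

#' Define a relation class
#'
#' A relation class is a named, directed link type with a forward and a
#' backward traversal label (e.g. "connects to" / "is connected from") and a
#' set of allowed (source, target) type pairs. The source of a pair may be a
#' relation class name, so experiments on connections can relate from a
#' connectivity relation; targets are always object types.
#'
#' @param kb a knowledge base.
#' @param name unique class name.
#' @param forward,backward traversal labels; must differ and be globally
#'   unique across classes so that a label resolves to exactly one class and
#'   direction.
#' @param allowed_pairs a data.frame with columns \code{source}, \code{target},
#'   or a list of length-2 character vectors.
#' @return The class definition, invisibly.
#' @export
kb_define_relation_class <- function(kb, name, forward, backward, allowed_pairs) {
  if (!is.null(kb$classes[[name]]))
    ckb_stop(sprintf("relation class '%s' is already defined", name),
             "ckb_definition_error")
  if (identical(tolower(forward), tolower(backward)))
    ckb_stop("forward and backward labels must differ", "ckb_definition_error")
  pairs <- normalize_pairs(allowed_pairs)
  if (nrow(pairs) == 0L)
    ckb_stop("allowed_pairs must be non-empty", "ckb_definition_error")
  for (lab in c(forward, backward)) {
    if (!is.null(kb$labels[[tolower(lab)]]))
      ckb_stop(sprintf("traversal label '%s' is already in use", lab),
               "ckb_definition_error")
  }
  def <- list(name = name, forward = forward, backward = backward,
              pairs = pairs, schemas = character())
  check_pair_endpoints(kb, name, pairs)
  kb$classes[[name]] <- def
  kb$labels[[tolower(forward)]] <- list(class = name, direction = "forward")
  kb$labels[[tolower(backward)]] <- list(class = name, direction = "backward")
  invisible(def)
}

normalize_pairs <- function(allowed_pairs) {
  if (is.data.frame(allowed_pairs)) {
    data.frame(source = as.character(allowed_pairs$source),
               target = as.character(allowed_pairs$target),
               stringsAsFactors = FALSE)
  } else if (is.list(allowed_pairs)) {
    data.frame(source = vapply(allowed_pairs, `[`, "", 1L),
               target = vapply(allowed_pairs, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    ckb_stop("allowed_pairs must be a data.frame or list of pairs",
             "ckb_definition_error")
  }
}

check_pair_endpoints <- function(kb, class_name, pairs) {
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$source[i]; t <- pairs$target[i]
    # source may name a type or a relation class (incl. the one being defined)
    if (is.null(kb$types[[s]]) && is.null(kb$classes[[s]]) && s != class_name)
      ckb_stop(sprintf("unknown source type or relation class '%s' in allowed_pairs", s),
               "ckb_definition_error")
    if (is.null(kb$types[[t]]))
      ckb_stop(sprintf("unknown target type '%s' in allowed_pairs", t),
               "ckb_definition_error")
  }
}

#' Allow an additional (source, target) pair on an existing relation class
#'
#' Used when new atlases or ontologies are loaded and become valid endpoints
#' of the generic parcellation / mapping classes.
#'
#' @param kb a knowledge base.
#' @param class_name relation class name.
#' @param source,target type (or, for source, relation class) names.
#' @export
kb_allow_pair <- function(kb, class_name, source, target) {
  def <- kb_class(kb, class_name)
  pairs <- rbind(def$pairs,
                 data.frame(source = source, target = target,
                            stringsAsFactors = FALSE))
  pairs <- unique(pairs)
  check_pair_endpoints(kb, class_name, pairs)
  kb$classes[[class_name]]$pairs <- pairs
  invisible(kb$classes[[class_name]])
}

kb_class <- function(kb, name) {
  d <- kb$classes[[name]]
  if (is.null(d))
    ckb_stop(sprintf("unknown relation class '%s'", name), "ckb_definition_error")
  d
}

#' Resolve a traversal label
#'
#' @param kb a knowledge base.
#' @param label a forward or backward relation label (case-insensitive).
#' @return \code{list(class, direction)} where direction is "forward" or
#'   "backward".
#' @export
kb_resolve_label <- function(kb, label) {
  hit <- kb$labels[[tolower(label)]]
  if (is.null(hit))
    ckb_stop(sprintf("traversal label '%s' does not resolve to a relation class", label),
             "ckb_query_error")
  hit
}

#' Create an instance of an object type
#'
#' @param kb a knowledge base.
#' @param type object type name (must exist).
#' @param id identifier, unique within the type (case-sensitive).
#' @param labels free-text labels, matched case-insensitively in queries.
#' @return The instance reference, invisibly.
#' @export
kb_create_instance <- function(kb, type, id, labels = character()) {
  kb_type(kb, type)
  ref <- ckb_ref(type, id)
  if (!is.null(kb$instances[[ref]]))
    ckb_stop(sprintf("instance '%s' of type '%s' already exists", id, type),
             "ckb_definition_error")
  kb$instances[[ref]] <- list(type = type, id = id,
                              labels = as.character(labels), ann = list())
  kb$inst_by_type[[type]] <- c(kb$inst_by_type[[type]], ref)
  invisible(ref)
}

#' Fetch an instance
#'
#' @param kb a knowledge base.
#' @param type type name.
#' @param id identifier.
#' @return The instance record: \code{list(type, id, labels, ann)}.
#' @export
kb_instance <- function(kb, type, id) {
  rec <- kb$instances[[ckb_ref(type, id)]]
  if (is.null(rec))
    ckb_stop(sprintf("no instance '%s' of type '%s'", id, type), "ckb_lookup_error")
  rec
}

#' @rdname kb_instance
#' @export
kb_has_instance <- function(kb, type, id) !is.null(kb$instances[[ckb_ref(type, id)]])

#' List the instance references of a type
#'
#' @param kb a knowledge base.
#' @param type type name.
#' @return Character vector of references (creation order).
#' @export
kb_instances <- function(kb, type) {
  kb_type(kb, type)
  refs <- kb$inst_by_type[[type]]
  if (is.null(refs)) character() else refs
}

rel_key <- function(class, source, target) paste(class, source, target, sep = .SEP)

#' Create (or fetch) a relation instance
#'
#' At most one relation instance exists per (class, source, target) triple;
#' relating the same triple again returns the existing instance. The endpoint
#' types must be an allowed pair of the class. Sources may be relation
#' references (relation-as-subject); targets must be instance references.
#'
#' @param kb a knowledge base.
#' @param class_name relation class name.
#' @param source,target instance references (source may be a relation
#'   reference).
#' @return The relation reference, invisibly.
#' @export
kb_relate <- function(kb, class_name, source, target) {
  def <- kb_class(kb, class_name)
  if (is_rel_ref(target))
    ckb_stop("relation targets must be object instances", "ckb_relation_error")
  stype <- endpoint_type(kb, source)
  ttype <- endpoint_type(kb, target)
  ok <- any(def$pairs$source == stype & def$pairs$target == ttype)
  if (!ok)
    ckb_stop(sprintf("pair (%s, %s) is not allowed for relation class '%s'",
                     stype, ttype, class_name), "ckb_relation_error")
  key <- rel_key(class_name, source, target)
  existing <- kb$rel_lookup[[key]]
  if (!is.null(existing)) return(invisible(existing))
  kb$rel_counter <- kb$rel_counter + 1L
  ref <- paste0("\x02", kb$rel_counter)
  kb$relations[[ref]] <- list(class = class_name, source = source,
                              target = target, ann = list())
  kb$rel_lookup[[key]] <- ref
  kb$rel_by_source[[source]] <- c(kb$rel_by_source[[source]], ref)
  kb$rel_by_target[[target]] <- c(kb$rel_by_target[[target]], ref)
  kb$rel_by_class[[class_name]] <- c(kb$rel_by_class[[class_name]], ref)
  invisible(ref)
}

endpoint_type <- function(kb, ref) {
  if (is_rel_ref(ref)) {
    rec <- kb$relations[[ref]]
    if (is.null(rec)) ckb_stop("unknown relation reference", "ckb_lookup_error")
    rec$class
  } else {
    rec <- kb$instances[[ref]]
    if (is.null(rec))
      ckb_stop(sprintf("unknown instance reference '%s'",
                       gsub(.SEP, "/", ref, fixed = TRUE)), "ckb_lookup_error")
    rec$type
  }
}

#' Fetch a relation record by reference
#'
#' @param kb a knowledge base.
#' @param ref a relation reference.
#' @return \code{list(class, source, target, ann)}.
#' @export
kb_relation <- function(kb, ref) {
  rec <- kb$relations[[ref]]
  if (is.null(rec)) ckb_stop("unknown relation reference", "ckb_lookup_error")
  rec
}

#' Find an existing relation instance
#'
#' @param kb a knowledge base.
#' @param class_name relation class name.
#' @param source,target endpoint references.
#' @return The relation reference, or \code{NULL} if absent.
#' @export
kb_find_relation <- function(kb, class_name, source, target) {
  kb$rel_lookup[[rel_key(class_name, source, target)]]
}

#' List relation references of a class
#'
#' @param kb a knowledge base.
#' @param class_name relation class name.
#' @export
kb_relations <- function(kb, class_name) {
  kb_class(kb, class_name)
  refs <- kb$rel_by_class[[class_name]]
  if (is.null(refs)) character() else refs
}

#' Traverse relations from an endpoint by label
#'
#' Follows the relation class identified by a forward or backward label and
#' returns the references of the opposite endpoints.
#'
#' @param kb a knowledge base.
#' @param ref instance (or relation) reference.
#' @param label forward or backward traversal label.
#' @return Character vector of endpoint references (possibly empty).
#' @export
kb_neighbors <- function(kb, ref, label) {
  hit <- kb_resolve_label(kb, label)
  if (hit$direction == "forward") {
    rels <- kb$rel_by_source[[ref]]
    side <- "target"
  } else {
    rels <- kb$rel_by_target[[ref]]
    side <- "source"
  }
  if (is.null(rels)) return(character())
  out <- character()
  for (r in rels) {
    rec <- kb$relations[[r]]
    if (rec$class == hit$class) out <- c(out, rec[[side]])
  }
  out
}

# ---- annotation schemas ----------------------------------------------------

VALUE_KINDS <- c("text", "integer", "real", "flag", "enumeration")

#' Define an annotation schema
#'
#' A schema names a set of attributes, each with a value kind (text, integer,
#' real, flag, enumeration), an optional numeric range and, for enumerations,
#' the allowed levels. Values annotated under the schema are validated
#' against it.
#'
#' @param kb a knowledge base.
#' @param name unique schema name.
#' @param attributes a list of attribute definitions, each
#'   \code{list(name, kind, range = NULL, levels = NULL)}. An empty list is a
#'   valid empty schema.
#' @return The schema definition, invisibly.
#' @export
kb_define_annotation_schema <- function(kb, name, attributes = list()) {
  if (!is.null(kb$schemas[[name]]))
    ckb_stop(sprintf("annotation schema '%s' is already defined", name),
             "ckb_definition_error")
  attrs <- list()
  for (a in attributes) {
    if (is.null(a$name) || is.null(a$kind))
      ckb_stop("each attribute needs a name and a kind", "ckb_definition_error")
    if (!a$kind %in% VALUE_KINDS)
      ckb_stop(sprintf("invalid value kind '%s'", a$kind), "ckb_definition_error")
    if (!is.null(attrs[[a$name]]))
      ckb_stop(sprintf("duplicate attribute name '%s'", a$name),
               "ckb_definition_error")
    attrs[[a$name]] <- list(name = a$name, kind = a$kind,
                            range = a$range, levels = a$levels)
  }
  def <- list(name = name, attributes = attrs)
  kb$schemas[[name]] <- def
  invisible(def)
}

#' Attach an annotation schema to an object type or relation class
#'
#' Annotation is only permitted on targets whose type (or class) carries the
#' schema.
#'
#' @param kb a knowledge base.
#' @param target_name an object type or relation class name.
#' @param schema_name schema name.
#' @export
kb_attach_schema <- function(kb, target_name, schema_name) {
  if (is.null(kb$schemas[[schema_name]]))
    ckb_stop(sprintf("unknown annotation schema '%s'", schema_name),
             "ckb_definition_error")
  if (!is.null(kb$types[[target_name]])) {
    kb$types[[target_name]]$schemas <-
      union(kb$types[[target_name]]$schemas, schema_name)
  } else if (!is.null(kb$classes[[target_name]])) {
    kb$classes[[target_name]]$schemas <-
      union(kb$classes[[target_name]]$schemas, schema_name)
  } else {
    ckb_stop(sprintf("unknown type or relation class '%s'", target_name),
             "ckb_definition_error")
  }
  invisible(NULL)
}

validate_attr_value <- function(schema, attr, value) {
  adef <- schema$attributes[[attr]]
  if (is.null(adef))
    ckb_stop(sprintf("schema '%s' has no attribute '%s'", schema$name, attr),
             "ckb_validation_error")
  kind <- adef$kind
  if (kind %in% c("integer", "real")) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value))
      ckb_stop(sprintf("attribute '%s' must be a single %s", attr, kind),
               "ckb_validation_error")
    if (kind == "integer" && value != round(value))
      ckb_stop(sprintf("attribute '%s' must be an integer", attr),
               "ckb_validation_error")
    if (!is.null(adef$range)) {
      lo <- adef$range[1]; hi <- adef$range[2]
      if (value < lo || value > hi)
        ckb_stop(sprintf("attribute '%s' value %g outside declared range [%g, %g]",
                         attr, value, lo, hi), "ckb_validation_error")
    }
  } else if (kind == "flag") {
    if (!(is.logical(value) && length(value) == 1L && !is.na(value)) &&
        !(is.numeric(value) && value %in% c(0, 1)))
      ckb_stop(sprintf("attribute '%s' must be a flag (0/1 or logical)", attr),
               "ckb_validation_error")
  } else if (kind == "enumeration") {
    if (!value %in% adef$levels)
      ckb_stop(sprintf("attribute '%s' value '%s' not among declared levels",
                       attr, value), "ckb_validation_error")
  } else {
    if (!is.character(value) || length(value) != 1L)
      ckb_stop(sprintf("attribute '%s' must be a single string", attr),
               "ckb_validation_error")
  }
  invisible(TRUE)
}

#' Annotate an instance or relation
#'
#' Stores a validated annotation value under a schema attached to the
#' target's type or relation class.
#'
#' @param kb a knowledge base.
#' @param ref instance or relation reference.
#' @param schema_name schema name (must be attached to the target's type or
#'   class).
#' @param values named list of attribute values.
#' @return The annotation value, invisibly.
#' @export
kb_annotate <- function(kb, ref, schema_name, values) {
  schema <- kb$schemas[[schema_name]]
  if (is.null(schema))
    ckb_stop(sprintf("unknown annotation schema '%s'", schema_name),
             "ckb_definition_error")
  tname <- endpoint_type(kb, ref)
  attached <- if (is_rel_ref(ref)) kb$classes[[tname]]$schemas
              else kb$types[[tname]]$schemas
  if (!schema_name %in% attached)
    ckb_stop(sprintf("schema '%s' is not attached to '%s'", schema_name, tname),
             "ckb_validation_error")
  if (length(values) && is.null(names(values)))
    ckb_stop("values must be a named list", "ckb_validation_error")
  for (attr in names(values)) validate_attr_value(schema, attr, values[[attr]])
  ann <- list(schema = schema_name, values = values)
  store <- if (is_rel_ref(ref)) kb$relations else kb$instances
  rec <- store[[ref]]
  rec$ann[[length(rec$ann) + 1L]] <- ann
  store[[ref]] <- rec
  invisible(ann)
}

#' Annotations of an instance or relation
#'
#' @param kb a knowledge base.
#' @param ref instance or relation reference.
#' @param schema_name optional filter by schema.
#' @return A list of annotation values (\code{list(schema, values)}).
#' @export
kb_annotations <- function(kb, ref, schema_name = NULL) {
  store <- if (is_rel_ref(ref)) kb$relations else kb$instances
  rec <- store[[ref]]
  if (is.null(rec)) ckb_stop("unknown reference", "ckb_lookup_error")
  ann <- rec$ann
  if (!is.null(schema_name))
    ann <- Filter(function(a) a$schema == schema_name, ann)
  ann
}

# ---- contexts --------------------------------------------------------------

#' Add an instance to a context
#'
#' Contexts group semantic objects (e.g. patients into a study, literature
#' into a brain structure). The context instance must be of a CONTEXT-kind
#' type. Membership is idempotent.
#'
#' @param kb a knowledge base.
#' @param context_ref reference of a CONTEXT-kind instance.
#' @param member_ref reference of the member instance.
#' @export
kb_add_to_context <- function(kb, context_ref, member_ref) {
  ctype <- endpoint_type(kb, context_ref)
  if (is_rel_ref(context_ref) || kb$types[[ctype]]$kind != "CONTEXT")
    ckb_stop(sprintf("'%s' is not a CONTEXT-kind instance", ctype),
             "ckb_validation_error")
  endpoint_type(kb, member_ref)  # existence check
  members <- kb$contexts[[context_ref]]
  if (!member_ref %in% members)
    kb$contexts[[context_ref]] <- c(members, member_ref)
  invisible(NULL)
}

#' @rdname kb_add_to_context
#' @return \code{kb_context_members} returns the member references.
#' @export
kb_context_members <- function(kb, context_ref) {
  m <- kb$contexts[[context_ref]]
  if (is.null(m)) character() else m
}

# ---- audits ----------------------------------------------------------------

#' Audit knowledge-base invariants
#'
#' Full-scan checks: every relation's endpoint types are allowed by its
#' class; every data entry's subject matches its method's subject spec and
#' its values lie within the declared format ranges.
#'
#' @param kb a knowledge base.
#' @return \code{TRUE} invisibly; errors on the first violation.
#' @export
kb_audit <- function(kb) {
  for (ref in ls(kb$relations)) {
    rec <- kb$relations[[ref]]
    def <- kb$classes[[rec$class]]
    st <- endpoint_type(kb, rec$source)
    tt <- endpoint_type(kb, rec$target)
    if (!any(def$pairs$source == st & def$pairs$target == tt))
      ckb_stop(sprintf("relation of class '%s' has disallowed pair (%s, %s)",
                       rec$class, st, tt), "ckb_audit_error")
  }
  for (key in ls(kb$entries)) {
    e <- kb$entries[[key]]
    m <- kb$methods[[e$method]]
    subj_type <- endpoint_type(kb, e$subject)
    if (subj_type != m$subject_name)
      ckb_stop(sprintf("entry subject type '%s' does not match method '%s' subject '%s'",
                       subj_type, e$method, m$subject_name), "ckb_audit_error")
    fmt <- m$formats[[e$format]]
    for (attr in names(e$values)) {
      adef <- fmt$attributes[[attr]]
      if (!is.null(adef$range) && is.numeric(e$values[[attr]])) {
        v <- e$values[[attr]]
        if (v < adef$range[1] || v > adef$range[2])
          ckb_stop(sprintf("entry value %g outside range of '%s'", v, e$format),
                   "ckb_audit_error")
      }
    }
  }
  invisible(TRUE)
}
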