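# Knowledge-base serialization: a single JSON document with stable ordering
# so exports diff cleanly and round trips are identity.

endpoint_content <- function(kb, ref) {
  if (is_rel_ref(ref)) {
    rec <- kb$relations[[ref]]
    list(relation = list(class = rec$class,
                         source = endpoint_content(kb, rec$source),
                         target = endpoint_content(kb, rec$target)))
  } else {
    rec <- kb$instances[[ref]]
    list(instance = list(type = rec$type, id = rec$id))
  }
}

content_key <- function(x) {
  if (!is.null(x$instance)) paste0("I:", x$instance$type, "/", x$instance$id)
  else paste0("R:", x$relation$class, "[", content_key(x$relation$source),
              ",", content_key(x$relation$target), "]")
}

ann_export <- function(ann) lapply(ann, function(a)
  list(schema = a$schema, values = a$values))

#' Export a knowledge base to a JSON document
#'
#' Sections: types, relation_classes, schemas, instances, relations,
#' contexts, methods, experiments, entries, ontologies. Instances,
#' relations, memberships and entries are sorted canonically so that two
#' exports of equal knowledge bases are byte-identical regardless of
#' creation order.
#'
#' @param kb a knowledge base.
#' @param path output file; when NULL, the JSON string is returned.
#' @return The path (or JSON string when \code{path} is NULL), invisibly.
#' @export
kb_save <- function(kb, path = NULL) {
  inst_refs <- sort(ls(kb$instances), method = "radix")
  instances <- lapply(inst_refs, function(r) {
    rec <- kb$instances[[r]]
    list(type = rec$type, id = rec$id, labels = as.list(rec$labels),
         annotations = ann_export(rec$ann))
  })
  rel_refs <- ls(kb$relations)
  rel_content <- lapply(rel_refs, function(r) {
    rec <- kb$relations[[r]]
    list(class = rec$class,
         source = endpoint_content(kb, rec$source),
         target = endpoint_content(kb, rec$target),
         annotations = ann_export(rec$ann))
  })
  rel_keys <- vapply(rel_content, function(x)
    content_key(list(relation = x)), "")
  rel_content <- rel_content[order(rel_keys, method = "radix")]

  ctx_refs <- sort(ls(kb$contexts), method = "radix")
  contexts <- lapply(ctx_refs, function(ctx) {
    members <- vapply(kb$contexts[[ctx]], function(m)
      content_key(endpoint_content(kb, m)), "")
    list(context = list(type = ref_type(kb, ctx), id = ref_id(ctx)),
         members = as.list(sort(members, method = "radix")))
  })

  exp_keys <- sort(ls(kb$experiments), method = "radix")
  experiments <- lapply(exp_keys, function(k) {
    e <- kb$experiments[[k]]
    list(method = e$method, name = e$name, metadata = e$metadata)
  })
  ent_keys <- ls(kb$entries)
  entries <- lapply(ent_keys, function(k) {
    e <- kb$entries[[k]]
    list(method = e$method, experiment = e$experiment,
         subject = endpoint_content(kb, e$subject), format = e$format,
         values = e$values)
  })
  ek <- vapply(entries, function(e)
    paste(e$method, e$experiment, content_key(e$subject), e$format,
          sep = "\x1f"), "")
  entries <- entries[order(ek, method = "radix")]

  classes <- lapply(kb$classes, function(d)
    list(name = d$name, forward = d$forward, backward = d$backward,
         pairs = d$pairs, schemas = as.list(d$schemas)))
  methods <- lapply(kb$methods, function(m)
    list(name = m$name, subject_kind = m$subject_kind,
         subject_name = m$subject_name,
         formats = lapply(m$formats, function(f)
           list(name = f$name,
                attributes = lapply(f$attributes, function(a)
                  list(name = a$name, kind = a$kind, range = a$range,
                       levels = a$levels)))),
         experiment_names = as.list(sort(m$experiment_names, method = "radix"))))
  schemas <- lapply(kb$schemas, function(s)
    list(name = s$name,
         attributes = lapply(s$attributes, function(a)
           list(name = a$name, kind = a$kind, range = a$range,
                levels = a$levels))))
  types <- lapply(kb$types, function(t)
    list(name = t$name, kind = t$kind, schemas = as.list(t$schemas)))
  ontologies <- lapply(kb$ontologies, function(o)
    list(parents = o$parents[sort(names(o$parents), method = "radix")]))

  doc <- list(format = "connectomekb/1", types = types,
              relation_classes = classes, schemas = schemas,
              instances = instances, relations = rel_content,
              contexts = contexts, methods = methods,
              experiments = experiments, entries = entries,
              ontologies = ontologies)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                          pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(txt, path)
  invisible(path)
}

resolve_content <- function(kb, x) {
  if (!is.null(x$instance)) return(ckb_ref(x$instance$type, x$instance$id))
  src <- resolve_content(kb, x$relation$source)
  tgt <- resolve_content(kb, x$relation$target)
  ref <- kb_find_relation(kb, x$relation$class, src, tgt)
  if (is.null(ref)) ref <- kb_relate(kb, x$relation$class, src, tgt)
  ref
}

num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))

#' Import a knowledge base from a JSON document
#'
#' Inverse of \code{\link{kb_save}}: type, instance, relation and annotation
#' sets (and experiment stores and ontologies) are reconstructed exactly;
#' counts are conserved.
#'
#' @param path a file path or JSON string.
#' @return A knowledge base.
#' @export
kb_load <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "connectomekb/1"))
    ckb_stop("not a connectomekb JSON document", "ckb_data_error")
  kb <- kb_new()
  for (t in doc$types) kb_define_object_type(kb, t$name, t$kind)
  for (s in doc$schemas) {
    kb_define_annotation_schema(kb, s$name, lapply(s$attributes, function(a)
      list(name = a$name, kind = a$kind, range = num_or_null(a$range),
           levels = if (is.null(a$levels)) NULL else unlist(a$levels))))
  }
  for (t in doc$types) for (sn in t$schemas) kb_attach_schema(kb, t$name, sn)
  for (cl in doc$relation_classes) {
    pairs <- data.frame(
      source = vapply(cl$pairs, function(p) p$source, ""),
      target = vapply(cl$pairs, function(p) p$target, ""),
      stringsAsFactors = FALSE)
    kb_define_relation_class(kb, cl$name, cl$forward, cl$backward, pairs)
  }
  for (cl in doc$relation_classes)
    for (sn in cl$schemas) kb_attach_schema(kb, cl$name, sn)
  for (inst in doc$instances) {
    ref <- kb_create_instance(kb, inst$type, inst$id, unlist(inst$labels))
    for (a in inst$annotations) kb_annotate(kb, ref, a$schema, a$values)
  }
  for (m in doc$methods) {
    kb_define_experiment_method(kb, m$name, m$subject_kind, m$subject_name,
      lapply(m$formats, function(f)
        format_def(f$name, lapply(f$attributes, function(a)
          list(name = a$name, kind = a$kind, range = num_or_null(a$range),
               levels = if (is.null(a$levels)) NULL else unlist(a$levels))))))
  }
  for (r in doc$relations) {
    ref <- resolve_content(kb, list(relation = r))
    for (a in r$annotations) kb_annotate(kb, ref, a$schema, a$values)
  }
  for (ctx in doc$contexts) {
    # members were exported as content keys of plain instances
    cref <- ckb_ref(ctx$context$type, ctx$context$id)
    for (m in ctx$members) {
      stopifnot(startsWith(m, "I:"))
      body <- sub("^I:", "", m)
      slash <- regexpr("/", body, fixed = TRUE)
      kb_add_to_context(kb, cref,
                        ckb_ref(substr(body, 1, slash - 1),
                                substr(body, slash + 1, nchar(body))))
    }
  }
  for (e in doc$experiments) kb_create_experiment(kb, e$method, e$name,
                                                  e$metadata)
  for (e in doc$entries) {
    subj <- resolve_content(kb, e$subject)
    kb_add_data_entry(kb, e$method, e$experiment, subj, e$format, e$values)
  }
  for (name in names(doc$ontologies)) {
    o <- doc$ontologies[[name]]
    parents <- lapply(o$parents, function(p) unlist(p))
    ids <- names(parents)
    children <- stats::setNames(vector("list", length(ids)), ids)
    for (ch in ids) for (pa in parents[[ch]])
      children[[pa]] <- union(children[[pa]], ch)
    roots <- ids[vapply(parents, length, 0L) == 0L]
    kb$ontologies[[name]] <- list(parents = parents, children = children,
                                  roots = roots)
  }
  kb
}
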