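# Atlases (flat listings), brain coordinates, ontologies with is-a edges,
# image-parcellation and brain-mapping relations, transitive closure.

#' Install the standard brain-science model
#'
#' Registers the object types, relation classes, annotation schemas and
#' experiment methods used by the connectome/transcriptome pipeline:
#' measured brain coordinates, the brain-structure repository, probes and
#' genes, the "measured brain connectivity" relation ("connects to" /
#' "is connected from"), probe-gene binding ("is detected by" / "binds to"),
#' the differential-gene-expression relation, and the DTI / rs-fMRI /
#' gene-expression experiment methods.
#'
#' @param kb a knowledge base.
#' @return The knowledge base, invisibly.
#' @export
kb_brain_model <- function(kb) {
  kb_define_object_type(kb, "patient", "ELEMENT")
  kb_define_object_type(kb, "measured brain coordinates", "ELEMENT")
  kb_define_object_type(kb, "brain structure", "CONTEXT")
  kb_define_object_type(kb, "study", "CONTEXT")
  kb_define_object_type(kb, "probe", "ELEMENT")
  kb_define_object_type(kb, "DNA", "CONTEXT")

  kb_define_annotation_schema(kb, "coordinate location", list(
    list(name = "frame", kind = "text"),
    list(name = "x", kind = "real"),
    list(name = "y", kind = "real"),
    list(name = "z", kind = "real")))
  kb_attach_schema(kb, "measured brain coordinates", "coordinate location")

  kb_define_relation_class(kb, "measured brain connectivity",
    "connects to", "is connected from",
    list(c("measured brain coordinates", "measured brain coordinates")))
  kb_define_relation_class(kb, "DNA to probe",
    "is detected by", "binds to",
    list(c("DNA", "probe")))
  kb_define_relation_class(kb, "differential gene expression",
    "is differentially expressed versus", "has differential expression from",
    list(c("brain structure", "brain structure")))
  kb_define_annotation_schema(kb, "DEG", list(
    list(name = "deg_count", kind = "real", range = c(0, Inf))))
  kb_attach_schema(kb, "differential gene expression", "DEG")

  kb_define_experiment_method(kb, "DTI", "RELATION_CLASS",
    "measured brain connectivity",
    c("normalized fiber density", "absolute fiber density", "probability"))
  kb_define_experiment_method(kb, "rs-fMRI", "RELATION_CLASS",
    "measured brain connectivity",
    c("normalized correlation value", "absolute correlation value"))
  kb_define_experiment_method(kb, "gene expression", "OBJECT_TYPE", "probe",
    list("expression level"))
  invisible(kb)
}

#' Register measured brain coordinates
#'
#' Each 3D location at which a measurement was taken becomes an individual
#' semantic object of type "measured brain coordinates", annotated with its
#' coordinate frame and millimetre position. Re-registering an existing
#' identifier is a no-op (coordinates accumulate across imports).
#'
#' @param kb a knowledge base (brain model installed).
#' @param coords data.frame with columns \code{identifier}, \code{x},
#'   \code{y}, \code{z} and optionally \code{label}.
#' @param frame coordinate frame, e.g. "MNI152"; must be non-empty.
#' @return Character vector of coordinate instance references.
#' @export
kb_add_coordinates <- function(kb, coords, frame = "MNI152") {
  if (!nzchar(frame)) ckb_stop("coordinate frame must be non-empty",
                               "ckb_validation_error")
  refs <- character(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    id <- as.character(coords$identifier[i])
    if (kb_has_instance(kb, "measured brain coordinates", id)) {
      refs[i] <- ckb_ref("measured brain coordinates", id)
      next
    }
    labels <- if ("label" %in% names(coords)) as.character(coords$label[i])
              else character()
    refs[i] <- kb_create_instance(kb, "measured brain coordinates", id, labels)
    kb_annotate(kb, refs[i], "coordinate location",
                list(frame = frame, x = as.numeric(coords$x[i]),
                     y = as.numeric(coords$y[i]), z = as.numeric(coords$z[i])))
  }
  refs
}

coordinate_frame <- function(kb, ref) {
  ann <- kb_annotations(kb, ref, "coordinate location")
  if (!length(ann)) return(NA_character_)
  ann[[1]]$values$frame
}

coordinate_xyz <- function(kb, ref) {
  ann <- kb_annotations(kb, ref, "coordinate location")
  if (!length(ann)) return(c(NA_real_, NA_real_, NA_real_))
  v <- ann[[1]]$values
  c(v$x, v$y, v$z)
}

#' Load a flat brain atlas
#'
#' Registers the atlas as a new ELEMENT-kind object type and creates one
#' entry instance per table row. The atlas becomes a valid parcellation
#' target (the "image parcellation" class is defined on first use).
#'
#' @param kb a knowledge base.
#' @param name atlas name (e.g. "Craddock200", "AAL").
#' @param table data.frame with columns \code{entry_id}, \code{label} (and
#'   optionally x, y, z, carried as labels only).
#' @return Character vector of entry references (one per row).
#' @export
kb_load_flat_atlas <- function(kb, name, table) {
  if (!all(c("entry_id", "label") %in% names(table)))
    ckb_stop("atlas table needs entry_id and label columns", "ckb_data_error")
  ids <- as.character(table$entry_id)
  if (anyDuplicated(ids))
    ckb_stop(sprintf("duplicate atlas entry id '%s'", ids[duplicated(ids)][1]),
             "ckb_data_error")
  kb_define_object_type(kb, name, "ELEMENT")
  if (is.null(kb$classes[["image parcellation"]])) {
    kb_define_relation_class(kb, "image parcellation", "belongs to",
                             "parcellates",
                             list(c("measured brain coordinates", name)))
  } else {
    kb_allow_pair(kb, "image parcellation", "measured brain coordinates", name)
  }
  refs <- character(nrow(table))
  for (i in seq_len(nrow(table)))
    refs[i] <- kb_create_instance(kb, name, ids[i],
                                  as.character(table$label[i]))
  refs
}

#' Load an ontology with is-a edges
#'
#' Registers the ontology as an ONTOLOGY-kind object type, creates one term
#' instance per row of \code{terms}, and stores the is-a graph (child to
#' parent; multiple parents allowed, so DAGs are supported). Acyclicity is
#' verified at load time.
#'
#' @param kb a knowledge base.
#' @param name ontology name.
#' @param terms data.frame with columns \code{term_id}, \code{name}.
#' @param edges data.frame with columns \code{child_id}, \code{parent_id};
#'   both sides must be declared terms.
#' @return The ontology name, invisibly.
#' @export
kb_load_ontology <- function(kb, name, terms, edges) {
  ids <- as.character(terms$term_id)
  if (anyDuplicated(ids))
    ckb_stop("duplicate ontology term ids", "ckb_data_error")
  kb_define_object_type(kb, name, "ONTOLOGY")
  for (i in seq_len(nrow(terms)))
    kb_create_instance(kb, name, ids[i], as.character(terms$name[i]))
  parents <- stats::setNames(vector("list", length(ids)), ids)
  children <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(edges)) {
    ch <- as.character(edges$child_id); pa <- as.character(edges$parent_id)
    bad <- setdiff(c(ch, pa), ids)
    if (length(bad))
      ckb_stop(sprintf("ontology edge references undeclared term '%s'", bad[1]),
               "ckb_data_error")
    for (i in seq_along(ch)) {
      parents[[ch[i]]] <- union(parents[[ch[i]]], pa[i])
      children[[pa[i]]] <- union(children[[pa[i]]], ch[i])
    }
  }
  # Kahn topological sort over child -> parent edges detects cycles
  indeg <- vapply(parents, length, 0L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (c in children[[t]]) {
      indeg_work[[c]] <- indeg_work[[c]] - 1L
      if (indeg_work[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids)) {
    member <- names(indeg_work)[indeg_work > 0L][1]
    ckb_stop(sprintf("is-a graph of ontology '%s' contains a cycle (involving term '%s')",
                     name, member), "ckb_data_error")
  }
  roots <- ids[vapply(parents[ids], length, 0L) == 0L]
  kb$ontologies[[name]] <- list(parents = parents, children = children,
                                roots = roots)
  invisible(name)
}

#' Root terms of an ontology
#'
#' @param kb a knowledge base.
#' @param ontology ontology name.
#' @return Character vector of parentless term ids.
#' @export
ontology_roots <- function(kb, ontology) {
  o <- kb$ontologies[[ontology]]
  if (is.null(o)) ckb_stop(sprintf("unknown ontology '%s'", ontology),
                           "ckb_lookup_error")
  o$roots
}

#' Transitive closure of is-a children ("is inferred from")
#'
#' Returns every term reachable from \code{term_id} by descending is-a
#' edges — the ontology expansion used to resolve fine-grained measurements
#' (e.g. gene expression in sub-regions) against coarse connectivity
#' structures.
#'
#' @param kb a knowledge base.
#' @param ontology ontology name.
#' @param term_id root of the descent; must exist.
#' @param include_self whether the root itself is a member of the result.
#' @return Character vector of term ids, sorted.
#' @export
ontology_descendants <- function(kb, ontology, term_id, include_self = FALSE) {
  o <- kb$ontologies[[ontology]]
  if (is.null(o)) ckb_stop(sprintf("unknown ontology '%s'", ontology),
                           "ckb_lookup_error")
  if (!term_id %in% names(o$children))
    ckb_stop(sprintf("unknown term '%s' in ontology '%s'", term_id, ontology),
             "ckb_lookup_error")
  seen <- new.env(parent = emptyenv())
  queue <- o$children[[term_id]]
  out <- character()
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (!is.null(seen[[t]])) next
    seen[[t]] <- TRUE
    out <- c(out, t)
    queue <- c(queue, o$children[[t]])
  }
  if (include_self) out <- c(out, term_id)
  sort(unique(out))
}

#' Relate coordinates to atlas entries (image parcellation)
#'
#' Creates one "belongs to" relation per lookup row. All coordinates must
#' share a single coordinate frame; the same coordinate may be parcellated
#' by several atlases simultaneously.
#'
#' @param kb a knowledge base.
#' @param lookup data.frame with columns \code{coord_id}, \code{entry_id}.
#' @param atlas atlas name (entries must exist).
#' @return Character vector of relation references.
#' @export
kb_parcellate_coordinates <- function(kb, lookup, atlas) {
  kb_type(kb, atlas)
  coord_refs <- ckb_ref("measured brain coordinates",
                        as.character(lookup$coord_id))
  frames <- vapply(coord_refs, function(r) {
    if (is.null(kb$instances[[r]]))
      ckb_stop(sprintf("unknown coordinate '%s'", ref_id(r)), "ckb_lookup_error")
    coordinate_frame(kb, r)
  }, "")
  if (length(unique(frames)) > 1L)
    ckb_stop(sprintf("parcellation mixes coordinate frames: %s",
                     paste(unique(frames), collapse = ", ")), "ckb_data_error")
  rels <- character(nrow(lookup))
  for (i in seq_len(nrow(lookup))) {
    entry <- ckb_ref(atlas, as.character(lookup$entry_id[i]))
    if (is.null(kb$instances[[entry]]))
      ckb_stop(sprintf("unknown atlas entry '%s' in '%s'",
                       lookup$entry_id[i], atlas), "ckb_lookup_error")
    rels[i] <- kb_relate(kb, "image parcellation", coord_refs[i], entry)
  }
  rels
}

#' Register brain structures
#'
#' The brain-structure repository is an independent set of canonical,
#' atlas-neutral structures that atlas entries and ontology terms map to.
#'
#' @param kb a knowledge base.
#' @param names character vector of canonical structure names (used as
#'   identifiers); existing names are skipped.
#' @return Character vector of structure references.
#' @export
kb_add_brain_structures <- function(kb, names) {
  vapply(names, function(n) {
    if (kb_has_instance(kb, "brain structure", n))
      ckb_ref("brain structure", n)
    else kb_create_instance(kb, "brain structure", n, n)
  }, "", USE.NAMES = FALSE)
}

#' Register brain mappings (atlas entry - structure - ontology term)
#'
#' Creates "maps to" relations from atlas entries to canonical brain
#' structures and, where ontology columns are present, from structures to
#' ontology terms, so that the chain coordinate - atlas entry - structure -
#' term is traversable in both directions. All endpoints must already exist;
#' the mapping is consumed as curated data ("best match"), never inferred.
#'
#' @param kb a knowledge base.
#' @param mapping data.frame with columns \code{atlas}, \code{entry_id},
#'   \code{structure_name} and optionally \code{ontology}, \code{term_id}.
#' @return Character vector of relation references.
#' @export
kb_register_brain_mapping <- function(kb, mapping) {
  if (is.null(kb$classes[["brain mapping"]])) {
    kb_define_relation_class(kb, "brain mapping", "maps to", "is mapped by",
                             list(c("brain structure", "brain structure")))
  }
  rels <- character()
  for (i in seq_len(nrow(mapping))) {
    st_ref <- ckb_ref("brain structure", as.character(mapping$structure_name[i]))
    if (is.null(kb$instances[[st_ref]]))
      ckb_stop(sprintf("mapping references undeclared brain structure '%s'",
                       mapping$structure_name[i]), "ckb_lookup_error")
    atlas <- as.character(mapping$atlas[i])
    if (nzchar(atlas) && !is.na(mapping$entry_id[i])) {
      entry_ref <- ckb_ref(atlas, as.character(mapping$entry_id[i]))
      if (is.null(kb$instances[[entry_ref]]))
        ckb_stop(sprintf("mapping references unknown atlas entry '%s' in '%s'",
                         mapping$entry_id[i], atlas), "ckb_lookup_error")
      kb_allow_pair(kb, "brain mapping", atlas, "brain structure")
      rels <- c(rels, kb_relate(kb, "brain mapping", entry_ref, st_ref))
    }
    if ("ontology" %in% names(mapping) && !is.na(mapping$ontology[i]) &&
        nzchar(as.character(mapping$ontology[i]))) {
      onto <- as.character(mapping$ontology[i])
      term_ref <- ckb_ref(onto, as.character(mapping$term_id[i]))
      if (is.null(kb$instances[[term_ref]]))
        ckb_stop(sprintf("mapping references unknown term '%s' in ontology '%s'",
                         mapping$term_id[i], onto), "ckb_lookup_error")
      kb_allow_pair(kb, "brain mapping", "brain structure", onto)
      rels <- c(rels, kb_relate(kb, "brain mapping", st_ref, term_ref))
    }
  }
  rels
}

# follow coordinate -> atlas entry -> structure -> ontology term; returns
# term ids (possibly several) or character() when the chain is broken
coord_to_terms <- function(kb, coord_ref, ontology, atlas = NULL) {
  entries <- kb_neighbors(kb, coord_ref, "belongs to")
  if (!is.null(atlas))
    entries <- entries[vapply(entries, function(e) ref_type(kb, e) == atlas, TRUE)]
  terms <- character()
  for (e in entries) {
    structs <- kb_neighbors(kb, e, "maps to")
    for (s in structs) {
      for (t in kb_neighbors(kb, s, "maps to")) {
        if (ref_type(kb, t) == ontology) terms <- c(terms, ref_id(t))
      }
    }
  }
  unique(terms)
}

# structures mapped to any of the given ontology terms
terms_to_structures <- function(kb, ontology, term_ids) {
  out <- character()
  for (tid in term_ids) {
    tref <- ckb_ref(ontology, tid)
    for (s in kb_neighbors(kb, tref, "is mapped by")) {
      if (ref_type(kb, s) == "brain structure") out <- c(out, s)
    }
  }
  unique(out)
}
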