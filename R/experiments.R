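# Subject-indexed measurement store: experiment methods with formats,
# experiments, data entries, and the subject-by-experiment tabulation.

#' Define an experiment format
#'
#' A format names the measured quantity and its attributes; each attribute
#' has a value kind and optional range that data entries are validated
#' against.
#'
#' @param name format name, e.g. "normalized correlation value".
#' @param attributes list of \code{list(name, kind, range = NULL)}; defaults
#'   to a single real attribute \code{value} with the range conventions of
#'   \code{\link{standard_formats}} when the name is recognised.
#' @return A format definition.
#' @export
format_def <- function(name, attributes = NULL) {
  if (is.null(attributes)) {
    std <- standard_formats()[[name]]
    if (!is.null(std)) return(std)
    attributes <- list(list(name = "value", kind = "real", range = NULL))
  }
  attrs <- list()
  for (a in attributes) {
    if (!is.null(attrs[[a$name]]))
      ckb_stop(sprintf("duplicate format attribute '%s'", a$name),
               "ckb_definition_error")
    attrs[[a$name]] <- list(name = a$name, kind = a$kind,
                            range = a$range, levels = a$levels)
  }
  list(name = name, attributes = attrs)
}

#' Standard measurement formats
#'
#' The connectivity and expression formats with their value ranges:
#' normalized correlation values lie in [-1, 1], normalized fiber densities
#' and tracking probabilities in [0, 1], absolute fiber densities are
#' non-negative, and expression levels carry a real log-intensity value plus
#' a PACall validity flag.
#'
#' @return Named list of format definitions.
#' @export
standard_formats <- function() {
  real_fmt <- function(name, range)
    list(name = name,
         attributes = list(value = list(name = "value", kind = "real",
                                        range = range, levels = NULL)))
  list(
    "normalized correlation value" = real_fmt("normalized correlation value", c(-1, 1)),
    "absolute correlation value"   = real_fmt("absolute correlation value", NULL),
    "normalized fiber density"     = real_fmt("normalized fiber density", c(0, 1)),
    "absolute fiber density"       = real_fmt("absolute fiber density", c(0, Inf)),
    "probability"                  = real_fmt("probability", c(0, 1)),
    "expression level" = list(
      name = "expression level",
      attributes = list(
        value  = list(name = "value", kind = "real", range = NULL, levels = NULL),
        pacall = list(name = "pacall", kind = "flag", range = NULL, levels = NULL))),
    "18FDG"            = real_fmt("18FDG", c(0, Inf)),
    "receptor density" = real_fmt("receptor density", c(0, Inf))
  )
}

#' Define an experiment method
#'
#' An experiment method fixes the subject every data entry is keyed by —
#' either an object type (e.g. patient, probe, measured brain coordinates)
#' or a relation class (e.g. measured brain connectivity, so that each entry
#' measures one connection) — and the formats it records.
#'
#' @param kb a knowledge base.
#' @param name unique method name.
#' @param subject_kind "OBJECT_TYPE" or "RELATION_CLASS".
#' @param subject_name the type or class name (must exist).
#' @param formats list of format definitions (see \code{\link{format_def}})
#'   or format names resolvable by \code{\link{standard_formats}}; at least
#'   one.
#' @return The method definition, invisibly.
#' @export
kb_define_experiment_method <- function(kb, name, subject_kind, subject_name,
                                        formats) {
  subject_kind <- match.arg(subject_kind, c("OBJECT_TYPE", "RELATION_CLASS"))
  if (!is.null(kb$methods[[name]]))
    ckb_stop(sprintf("experiment method '%s' is already defined", name),
             "ckb_definition_error")
  if (subject_kind == "OBJECT_TYPE") kb_type(kb, subject_name)
  else kb_class(kb, subject_name)
  if (length(formats) == 0L)
    ckb_stop("an experiment method needs at least one format",
             "ckb_definition_error")
  fmts <- list()
  for (f in formats) {
    if (is.character(f)) f <- format_def(f)
    if (!is.null(fmts[[f$name]]))
      ckb_stop(sprintf("duplicate format '%s'", f$name), "ckb_definition_error")
    fmts[[f$name]] <- f
  }
  def <- list(name = name, subject_kind = subject_kind,
              subject_name = subject_name, formats = fmts,
              experiment_names = character())
  kb$methods[[name]] <- def
  invisible(def)
}

kb_method <- function(kb, name) {
  m <- kb$methods[[name]]
  if (is.null(m))
    ckb_stop(sprintf("unknown experiment method '%s'", name),
             "ckb_definition_error")
  m
}

exp_key <- function(method, name) paste(method, name, sep = .SEP)

#' Create an experiment under a method
#'
#' Experiment names are unique within their method (the same name may recur
#' under a different method). Metadata (donor id, protocol, source file) is
#' stored as a named list.
#'
#' @param kb a knowledge base.
#' @param method method name.
#' @param name experiment name.
#' @param metadata named list of free-form metadata.
#' @return The experiment record, invisibly.
#' @export
kb_create_experiment <- function(kb, method, name, metadata = list()) {
  kb_method(kb, method)
  key <- exp_key(method, name)
  if (!is.null(kb$experiments[[key]]))
    ckb_stop(sprintf("experiment '%s' already exists under method '%s'",
                     name, method), "ckb_definition_error")
  rec <- list(method = method, name = name, metadata = metadata)
  kb$experiments[[key]] <- rec
  kb$methods[[method]]$experiment_names <-
    c(kb$methods[[method]]$experiment_names, name)
  invisible(rec)
}

#' @rdname kb_create_experiment
#' @export
kb_experiment <- function(kb, method, name) {
  rec <- kb$experiments[[exp_key(method, name)]]
  if (is.null(rec))
    ckb_stop(sprintf("no experiment '%s' under method '%s'", name, method),
             "ckb_lookup_error")
  rec
}

entry_key <- function(method, experiment, subject, fmt)
  paste(method, experiment, subject, fmt, sep = .SEP)

#' Add a data entry to an experiment
#'
#' One entry holds one format's values for one subject in one experiment.
#' The subject must match the method's subject spec (an instance of the
#' subject type, or a relation of the subject class), and values are
#' validated against the format's attribute kinds and ranges. Overwriting an
#' existing (experiment, subject, format) entry is an error unless
#' \code{replace = TRUE}.
#'
#' @param kb a knowledge base.
#' @param method,experiment method and experiment names.
#' @param subject instance or relation reference, per the method's subject
#'   spec.
#' @param format_name one of the method's formats.
#' @param values named list of attribute values; a bare scalar is taken as
#'   the format's first attribute.
#' @param replace replace an existing entry instead of erroring.
#' @return The entry key, invisibly.
#' @export
kb_add_data_entry <- function(kb, method, experiment, subject, format_name,
                              values, replace = FALSE) {
  m <- kb_method(kb, method)
  kb_experiment(kb, method, experiment)
  subj_type <- endpoint_type(kb, subject)
  if (m$subject_kind == "RELATION_CLASS") {
    if (!is_rel_ref(subject) || subj_type != m$subject_name)
      ckb_stop(sprintf("subject must be a '%s' relation", m$subject_name),
               "ckb_validation_error")
  } else {
    if (is_rel_ref(subject) || subj_type != m$subject_name)
      ckb_stop(sprintf("subject must be an instance of '%s'", m$subject_name),
               "ckb_validation_error")
  }
  fmt <- m$formats[[format_name]]
  if (is.null(fmt))
    ckb_stop(sprintf("method '%s' has no format '%s'", method, format_name),
             "ckb_validation_error")
  if (!is.list(values)) {
    values <- stats::setNames(list(values), names(fmt$attributes)[1])
  }
  for (attr in names(values)) validate_attr_value(fmt, attr, values[[attr]])
  key <- entry_key(method, experiment, subject, format_name)
  if (!is.null(kb$entries[[key]]) && !replace)
    ckb_stop("entry already exists for this (experiment, subject, format); use replace = TRUE",
             "ckb_validation_error")
  new_entry <- is.null(kb$entries[[key]])
  kb$entries[[key]] <- list(method = method, experiment = experiment,
                            subject = subject, format = format_name,
                            values = values)
  if (new_entry) {
    mkey <- paste(method, subject, sep = .SEP)
    kb$entries_by_msub[[mkey]] <- c(kb$entries_by_msub[[mkey]], key)
  }
  invisible(key)
}

#' Look up a stored value for a subject under a method
#'
#' @param kb a knowledge base.
#' @param method method name.
#' @param subject subject reference.
#' @param attr attribute name; defaults to the first attribute of the format.
#' @param format_name optional filter by format.
#' @param experiment optional filter by experiment name.
#' @return The first matching value, or \code{NA} if no entry exists
#'   (missing measurements are absent entries, never sentinels).
#' @export
kb_entry_value <- function(kb, method, subject, attr = NULL,
                           format_name = NULL, experiment = NULL) {
  keys <- kb$entries_by_msub[[paste(method, subject, sep = .SEP)]]
  if (is.null(keys)) return(NA_real_)
  for (key in keys) {
    e <- kb$entries[[key]]
    if (!is.null(format_name) && e$format != format_name) next
    if (!is.null(experiment) && e$experiment != experiment) next
    a <- if (is.null(attr)) names(e$values)[1] else attr
    v <- e$values[[a]]
    if (!is.null(v)) return(v)
  }
  NA_real_
}

#' Entries stored under a method
#'
#' @param kb a knowledge base.
#' @param method method name.
#' @return List of entry records.
#' @export
kb_method_entries <- function(kb, method) {
  kb_method(kb, method)
  keys <- ls(kb$entries)
  out <- list()
  for (key in keys) {
    e <- kb$entries[[key]]
    if (e$method == method) out[[length(out) + 1L]] <- e
  }
  out
}

#' Tabulate a method as subjects-by-experiments
#'
#' Expands a method's entries into a matrix-shaped data.frame with one row
#' per distinct subject and one column per experiment name; cells carry the
#' primary value (the first attribute of the entry's format, overridable by
#' name) or \code{NA} where no measurement exists.
#'
#' @param kb a knowledge base.
#' @param method method name.
#' @param experiments optional subset of experiment names (default: all, in
#'   creation order).
#' @param value_attr attribute to place in cells; default first attribute.
#' @return A data.frame with a \code{subject} column followed by one column
#'   per experiment.
#' @export
kb_tabulate <- function(kb, method, experiments = NULL, value_attr = NULL) {
  m <- kb_method(kb, method)
  if (is.null(experiments)) experiments <- m$experiment_names
  entries <- kb_method_entries(kb, method)
  subj_label <- function(ref) {
    if (is_rel_ref(ref)) {
      rec <- kb$relations[[ref]]
      paste0(ref_id(rec$source), "->", ref_id(rec$target))
    } else ref_id(ref)
  }
  subjects <- character(); seen <- new.env(parent = emptyenv())
  for (e in entries) {
    if (is.null(seen[[e$subject]])) {
      seen[[e$subject]] <- TRUE
      subjects <- c(subjects, e$subject)
    }
  }
  subjects <- sort(subjects)
  tab <- data.frame(subject = vapply(subjects, subj_label, ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (ex in experiments) tab[[ex]] <- NA_real_
  if (length(subjects)) {
    idx <- stats::setNames(seq_along(subjects), subjects)
    for (e in entries) {
      if (!e$experiment %in% experiments) next
      a <- if (is.null(value_attr)) names(e$values)[1] else value_attr
      v <- e$values[[a]]
      if (!is.null(v)) tab[idx[[e$subject]], e$experiment] <- v
    }
  }
  tab
}

#' Export a method's entries as a long-form table
#'
#' @param kb a knowledge base.
#' @param method method name.
#' @return data.frame with columns method, experiment, subject, format,
#'   attr, value.
#' @export
kb_entries_long <- function(kb, method) {
  entries <- kb_method_entries(kb, method)
  rows <- list()
  for (e in entries) {
    subj <- if (is_rel_ref(e$subject)) {
      rec <- kb$relations[[e$subject]]
      paste0(ref_id(rec$source), "->", ref_id(rec$target))
    } else ref_id(e$subject)
    for (attr in names(e$values)) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = e$method, experiment = e$experiment, subject = subj,
        format = e$format, attr = attr,
        value = as.character(e$values[[attr]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(method = character(), experiment = character(),
                      subject = character(), format = character(),
                      attr = character(), value = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$experiment, out$subject, out$format, out$attr), , drop = FALSE]
}
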