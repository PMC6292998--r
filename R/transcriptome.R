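# Gene-expression and differential-expression ingestion, localized
# expression filters, and the cross-modal connectivity-by-DEG join.

#' Import probe-level gene expression (Allen microarray style)
#'
#' Creates one gene-expression experiment per (donor, location), one data
#' entry per probe measurement (format "expression level": value + PACall
#' flag), probe and gene objects, and "DNA to probe" relations ("is detected
#' by" / "binds to"). A probe listing several gene symbols is related to
#' each of them.
#'
#' @param kb a knowledge base with the brain model installed.
#' @param table data.frame with columns \code{donor}, \code{structure_id}
#'   (and/or \code{mni_x}, \code{mni_y}, \code{mni_z}), \code{probe_id},
#'   \code{gene_symbol} (multiple symbols separated by ";"),
#'   \code{expression}, \code{pacall}.
#' @param method experiment method name (defined by the brain model).
#' @return list(experiments, entries) counts, invisibly.
#' @export
import_expression <- function(kb, table, method = "gene expression") {
  kb_method(kb, method)
  pac <- table$pacall
  if (any(is.na(pac)) || !all(pac %in% c(0, 1)))
    ckb_stop("pacall values must be 0 or 1", "ckb_data_error")
  loc <- if (!is.null(table$structure_id)) as.character(table$structure_id)
         else sprintf("(%g,%g,%g)", table$mni_x, table$mni_y, table$mni_z)
  exp_names <- paste(as.character(table$donor), loc, sep = "|")
  n_exp <- 0L; n_ent <- 0L
  for (en in unique(exp_names)) {
    i0 <- which(exp_names == en)[1]
    kb_create_experiment(kb, method, en,
                         metadata = list(donor = as.character(table$donor[i0]),
                                         location = loc[i0]))
    n_exp <- n_exp + 1L
  }
  for (i in seq_len(nrow(table))) {
    pid <- as.character(table$probe_id[i])
    if (!kb_has_instance(kb, "probe", pid))
      kb_create_instance(kb, "probe", pid)
    probe_ref <- ckb_ref("probe", pid)
    genes <- strsplit(as.character(table$gene_symbol[i]), ";", fixed = TRUE)[[1]]
    genes <- trimws(genes[nzchar(trimws(genes))])
    for (g in genes) {
      if (!kb_has_instance(kb, "DNA", g))
        kb_create_instance(kb, "DNA", g, g)
      kb_relate(kb, "DNA to probe", ckb_ref("DNA", g), probe_ref)
    }
    kb_add_data_entry(kb, method, exp_names[i], probe_ref, "expression level",
                      list(value = as.numeric(table$expression[i]),
                           pacall = as.numeric(pac[i])))
    n_ent <- n_ent + 1L
  }
  invisible(list(experiments = n_exp, entries = n_ent))
}

#' Localized expression of a gene
#'
#' Finds all (probe, location) measurements for probes binding the gene,
#' keeping values strictly greater than \code{min_value} (the printed
#' "greater than 8" on the data's native log-intensity scale) and, when
#' required, a PACall flag of 1 (signal significantly above background).
#'
#' @param kb a knowledge base.
#' @param gene gene symbol (a DNA object); unknown genes are an error.
#' @param min_value strict lower bound on the expression value.
#' @param require_pacall require PACall == 1.
#' @param method gene-expression method name.
#' @return data.frame (donor, location, probe, value, pacall), sorted by
#'   value descending.
#' @export
localized_expression <- function(kb, gene, min_value = 8,
                                 require_pacall = TRUE,
                                 method = "gene expression") {
  gref <- ckb_ref("DNA", gene)
  if (is.null(kb$instances[[gref]]))
    ckb_stop(sprintf("unknown gene '%s'", gene), "ckb_lookup_error")
  probes <- kb_neighbors(kb, gref, "is detected by")
  rows <- list()
  for (p in probes) {
    keys <- kb$entries_by_msub[[paste(method, p, sep = .SEP)]]
    for (key in keys) {
      e <- kb$entries[[key]]
      v <- e$values$value
      if (is.null(v) || v <= min_value) next
      if (require_pacall && !identical(as.numeric(e$values$pacall), 1)) next
      meta <- kb_experiment(kb, method, e$experiment)$metadata
      rows[[length(rows) + 1L]] <- data.frame(
        donor = if (is.null(meta$donor)) NA_character_ else meta$donor,
        location = if (is.null(meta$location)) e$experiment else meta$location,
        probe = ref_id(p), value = v,
        pacall = as.numeric(e$values$pacall), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor = character(), location = character(),
                      probe = character(), value = numeric(),
                      pacall = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$value, out$probe, out$location), , drop = FALSE]
}

deg_pair_key <- function(a, b) {
  p <- sort(c(a, b))
  paste(p[1], p[2], sep = .SEP)
}

#' Import differential-gene-expression pair counts
#'
#' One annotated "differential gene expression" relation per unordered
#' structure pair, carrying the number of differentially expressed genes;
#' querying (B, A) returns the (A, B) value. Counts must be non-negative,
#' and re-importing a pair with a conflicting count is an error.
#'
#' @param kb a knowledge base.
#' @param pair_table data.frame with columns \code{structure_a},
#'   \code{structure_b}, \code{deg_count}.
#' @return Number of relations created, invisibly.
#' @export
import_deg <- function(kb, pair_table) {
  counts <- as.numeric(pair_table$deg_count)
  if (any(is.na(counts)) || any(counts < 0))
    ckb_stop("DEG counts must be non-negative", "ckb_data_error")
  n <- 0L
  for (i in seq_len(nrow(pair_table))) {
    a <- as.character(pair_table$structure_a[i])
    b <- as.character(pair_table$structure_b[i])
    p <- sort(c(a, b))
    aref <- ckb_ref("brain structure", p[1])
    bref <- ckb_ref("brain structure", p[2])
    for (r in c(aref, bref)) endpoint_type(kb, r)  # structures must exist
    existing <- kb_find_relation(kb, "differential gene expression", aref, bref)
    if (!is.null(existing)) {
      old <- kb_annotations(kb, existing, "DEG")[[1]]$values$deg_count
      if (!isTRUE(all.equal(old, counts[i])))
        ckb_stop(sprintf("conflicting DEG count for pair (%s, %s): %g vs %g",
                         a, b, old, counts[i]), "ckb_data_error")
      next
    }
    rel <- kb_relate(kb, "differential gene expression", aref, bref)
    kb_annotate(kb, rel, "DEG", list(deg_count = counts[i]))
    n <- n + 1L
  }
  invisible(n)
}

#' Look up a DEG count between two structures (symmetric)
#'
#' @param kb a knowledge base.
#' @param a,b structure names, in either order.
#' @return The count, or \code{NA} if no DEG link exists.
#' @export
kb_deg_count <- function(kb, a, b) {
  p <- sort(c(a, b))
  rel <- kb_find_relation(kb, "differential gene expression",
                          ckb_ref("brain structure", p[1]),
                          ckb_ref("brain structure", p[2]))
  if (is.null(rel)) return(NA_real_)
  kb_annotations(kb, rel, "DEG")[[1]]$values$deg_count
}

#' Cross-modal join of connectivity and differential gene expression
#'
#' For every measured-brain-connectivity relation whose endpoints resolve
#' (coordinate - atlas entry - brain structure - ontology term) to terms O
#' and T, collects all DEG links whose endpoints lie in the structures
#' mapped to descendants(O) x descendants(T); without descendant expansion
#' (\code{descend = FALSE}) only the directly mapped structures join — the
#' configuration in which gross-scale connectivity against fine-grained
#' expression returns nothing. Each unordered structure pair is counted
#' once; the DEG average is the arithmetic mean of the collected counts.
#' Connections with no matched DEG link are excluded; connections whose
#' mapping chain is broken are skipped with a warning. One output row per
#' connectivity relation, so several coordinates sharing labels yield
#' several (duplicate-looking) rows.
#'
#' @param kb a knowledge base.
#' @param structural_method,functional_method experiment method names.
#' @param ontology ontology name used for the descent.
#' @param atlas optional atlas restriction for parcellation.
#' @param include_self whether the resolved term itself belongs to its
#'   descendant set (default TRUE, so structures with direct DEG links and
#'   no sub-regions still join).
#' @param descend expand terms to their is-a descendants (default TRUE).
#' @return data.frame of connection records: origin, target, coordinates,
#'   structural, functional, deg_avg, n_subpairs. Skipped connections are
#'   reported in attribute "skipped".
#' @export
crossmodal_join <- function(kb, structural_method = "DTI",
                            functional_method = "rs-fMRI", ontology,
                            atlas = NULL, include_self = TRUE,
                            descend = TRUE) {
  rels <- kb_relations(kb, "measured brain connectivity")
  term_cache <- new.env(parent = emptyenv())
  struct_cache <- new.env(parent = emptyenv())
  side_structures <- function(coord) {
    hit <- term_cache[[coord]]
    if (!is.null(hit)) return(hit)
    terms <- coord_to_terms(kb, coord, ontology, atlas)
    structs <- character()
    for (t in terms) {
      key <- paste0(t, if (descend) "+d" else "")
      st <- struct_cache[[key]]
      if (is.null(st)) {
        expanded <- if (descend)
          ontology_descendants(kb, ontology, t, include_self = include_self)
        else if (include_self) t else character()
        st <- terms_to_structures(kb, ontology, expanded)
        struct_cache[[key]] <- st
      }
      structs <- c(structs, st)
    }
    out <- unique(structs)
    term_cache[[coord]] <- out
    out
  }
  rows <- list(); skipped <- 0L
  for (rel in rels) {
    rec <- kb$relations[[rel]]
    o_structs <- side_structures(rec$source)
    t_structs <- side_structures(rec$target)
    if (!length(o_structs) || !length(t_structs)) {
      skipped <- skipped + 1L
      next
    }
    seen <- new.env(parent = emptyenv())
    counts <- numeric()
    for (a in o_structs) for (b in t_structs) {
      key <- deg_pair_key(ref_id(a), ref_id(b))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cnt <- kb_deg_count(kb, ref_id(a), ref_id(b))
      if (!is.na(cnt)) counts <- c(counts, cnt)
    }
    if (!length(counts)) next
    src <- kb$instances[[rec$source]]; tgt <- kb$instances[[rec$target]]
    sxyz <- coordinate_xyz(kb, rec$source)
    txyz <- coordinate_xyz(kb, rec$target)
    rows[[length(rows) + 1L]] <- data.frame(
      origin = if (length(src$labels)) src$labels[1] else src$id,
      target = if (length(tgt$labels)) tgt$labels[1] else tgt$id,
      origin_id = src$id, target_id = tgt$id,
      origin_x = sxyz[1], origin_y = sxyz[2], origin_z = sxyz[3],
      target_x = txyz[1], target_y = txyz[2], target_z = txyz[3],
      structural = kb_entry_value(kb, structural_method, rel),
      functional = kb_entry_value(kb, functional_method, rel),
      deg_avg = mean(counts), n_subpairs = length(counts),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(sprintf("%d connection(s) skipped: endpoint mapping chain missing",
                    skipped), call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(origin = character(), target = character(),
               origin_id = character(), target_id = character(),
               origin_x = numeric(), origin_y = numeric(), origin_z = numeric(),
               target_x = numeric(), target_y = numeric(), target_z = numeric(),
               structural = numeric(), functional = numeric(),
               deg_avg = numeric(), n_subpairs = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$origin_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Threshold connection records
#'
#' Each threshold is applied only when given; records lacking a filtered
#' field fail that filter. Comparisons follow the printed inequalities:
#' structural and functional minima and the DEG maximum are inclusive
#' (>= / <=), while \code{min_deg} is strict (> 200 selects counts above
#' 200). Record order is preserved; tightening any bound never enlarges the
#' result.
#'
#' @param records data.frame with columns \code{structural},
#'   \code{functional}, \code{deg_avg} (any may be NA).
#' @param min_struct,min_func inclusive lower bounds.
#' @param max_deg inclusive upper bound on the DEG average.
#' @param min_deg strict lower bound on the DEG average.
#' @return The filtered subset.
#' @export
filter_connections <- function(records, min_struct = NULL, min_func = NULL,
                               max_deg = NULL, min_deg = NULL) {
  chk_range <- function(v, lo, hi, what) {
    if (!is.null(v) && (!is.numeric(v) || is.na(v) || v < lo || v > hi))
      ckb_stop(sprintf("%s threshold must lie in [%g, %g]", what, lo, hi),
               "ckb_validation_error")
  }
  chk_range(min_struct, 0, 1, "structural")
  chk_range(min_func, -1, 1, "functional")
  chk_range(max_deg, 0, Inf, "DEG")
  chk_range(min_deg, 0, Inf, "DEG")
  keep <- rep(TRUE, nrow(records))
  pass <- function(x, f) !is.na(x) & f(x)
  if (!is.null(min_struct)) keep <- keep & pass(records$structural,
                                                function(x) x >= min_struct)
  if (!is.null(min_func)) keep <- keep & pass(records$functional,
                                              function(x) x >= min_func)
  if (!is.null(max_deg)) keep <- keep & pass(records$deg_avg,
                                             function(x) x <= max_deg)
  if (!is.null(min_deg)) keep <- keep & pass(records$deg_avg,
                                             function(x) x > min_deg)
  records[keep, , drop = FALSE]
}
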