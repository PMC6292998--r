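# Connectivity-matrix import as relation-subject experiments, functional
# brain network (FBN) template extraction, functional classification, and
# styled lattice-graph export.

#' Wrap a connectivity matrix for import
#'
#' @param values n-by-n numeric matrix of connection strengths.
#' @param labels length-n character vector of region labels (may repeat:
#'   several coordinates can share an anatomical label).
#' @param coordinates data.frame with columns \code{x}, \code{y}, \code{z}
#'   (MNI millimetres) and optionally \code{identifier}; identifiers default
#'   to "(x,y,z)" strings, which makes coordinate identity exact-match on
#'   position.
#' @param modality experiment method name, e.g. "DTI" or "rs-fMRI".
#' @param format_name measurement format, e.g. "normalized fiber density" or
#'   "normalized correlation value".
#' @param symmetric declared symmetry; when NULL, detected from the matrix
#'   (equality with its transpose within 1e-9).
#' @param frame coordinate frame name.
#' @return An object of class \code{connectivity_input}.
#' @export
connectivity_input <- function(values, labels, coordinates, modality,
                               format_name, symmetric = NULL,
                               frame = "MNI152") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n)
    ckb_stop("connectivity matrix must be square", "ckb_data_error")
  if (length(labels) != n || nrow(coordinates) != n)
    ckb_stop("matrix, labels and coordinates dimensions disagree",
             "ckb_data_error")
  is_sym <- max(abs(values - t(values))) <= 1e-9
  if (is.null(symmetric)) symmetric <- is_sym
  if (symmetric && !is_sym)
    ckb_stop("matrix declared symmetric but differs from its transpose (tolerance 1e-9)",
             "ckb_data_error")
  if (is.null(coordinates$identifier))
    coordinates$identifier <- sprintf("(%g,%g,%g)", coordinates$x,
                                      coordinates$y, coordinates$z)
  structure(list(values = values, labels = as.character(labels),
                 coordinates = coordinates, symmetric = symmetric,
                 modality = modality, format_name = format_name,
                 frame = frame),
            class = "connectivity_input")
}

#' Read a connectivity matrix and region file (USC MCD style)
#'
#' The matrix file is a whitespace- or comma-separated n-by-n table; the
#' region file has one region per line: label, x, y, z.
#'
#' @param matrix_file path to the matrix file.
#' @param region_file path to the region/coordinate file.
#' @param modality,format_name,symmetric,frame passed to
#'   \code{\link{connectivity_input}}.
#' @return A \code{connectivity_input}.
#' @export
read_connectivity_matrix <- function(matrix_file, region_file, modality,
                                     format_name, symmetric = NULL,
                                     frame = "MNI152") {
  first <- readLines(matrix_file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  values <- as.matrix(utils::read.table(matrix_file, sep = sep,
                                        header = FALSE, quote = ""))
  dimnames(values) <- NULL
  rlines <- readLines(region_file)
  rlines <- rlines[nzchar(trimws(rlines))]
  rsep <- if (grepl(",", rlines[1], fixed = TRUE)) "," else "[[:space:]]+"
  # labels may contain spaces; the last three fields are x, y, z
  parsed <- lapply(strsplit(trimws(rlines), rsep), function(fields) {
    if (length(fields) < 4)
      ckb_stop("region file rows need label plus x, y, z", "ckb_data_error")
    n <- length(fields)
    xyz <- suppressWarnings(as.numeric(fields[(n - 2):n]))
    if (anyNA(xyz))
      ckb_stop("region file coordinates must be numeric", "ckb_data_error")
    list(label = paste(fields[1:(n - 3)], collapse = " "), xyz = xyz)
  })
  regions <- data.frame(
    label = vapply(parsed, `[[`, "", "label"),
    x = vapply(parsed, function(p) p$xyz[1], 0),
    y = vapply(parsed, function(p) p$xyz[2], 0),
    z = vapply(parsed, function(p) p$xyz[3], 0),
    stringsAsFactors = FALSE)
  connectivity_input(values, regions$label,
                     regions[, c("x", "y", "z")], modality, format_name,
                     symmetric = symmetric, frame = frame)
}

#' Import a connectivity matrix into the knowledge base
#'
#' Every off-diagonal cell becomes (a) a "measured brain connectivity"
#' relation between the two coordinate objects and (b) a data entry on that
#' relation in an experiment of the input's modality. Symmetric matrices are
#' stored as one canonical directed relation per unordered pair (source =
#' ascending coordinate identifier) — traversal works in both directions and
#' double storage would double join counts; asymmetric matrices keep one
#' relation per ordered pair. Relations are shared across modalities:
#' re-importing a second modality on the same coordinates adds entries, not
#' relations. Diagonal cells (a coordinate with itself) are always dropped.
#'
#' @param kb a knowledge base with the brain model installed.
#' @param input a \code{\link{connectivity_input}}.
#' @param experiment_name experiment name under the modality's method;
#'   defaults to "<modality> import".
#' @param zero_policy "keep" or "drop" for exact-zero cells. Default NULL
#'   infers from the format: zeros are kept for correlation formats (zero
#'   correlation is informative) and dropped for fiber density/probability
#'   (zero means no tract).
#' @return list(experiment, relations_created, entries_created,
#'   coordinate_refs) invisibly.
#' @export
import_connectivity_matrix <- function(kb, input, experiment_name = NULL,
                                       zero_policy = NULL) {
  stopifnot(inherits(input, "connectivity_input"))
  if (is.null(zero_policy)) {
    zero_policy <- if (grepl("correlation", input$format_name)) "keep" else "drop"
  }
  zero_policy <- match.arg(zero_policy, c("keep", "drop"))
  if (is.null(experiment_name))
    experiment_name <- paste(input$modality, "import")
  kb_method(kb, input$modality)

  coords <- input$coordinates
  coords$label <- input$labels
  # frame consistency: all existing coordinate objects must share the frame
  for (id in as.character(coords$identifier)) {
    ref <- ckb_ref("measured brain coordinates", id)
    if (!is.null(kb$instances[[ref]])) {
      fr <- coordinate_frame(kb, ref)
      if (!is.na(fr) && fr != input$frame)
        ckb_stop(sprintf("coordinate '%s' already registered in frame '%s' (import frame '%s')",
                         id, fr, input$frame), "ckb_data_error")
    }
  }
  refs <- kb_add_coordinates(kb, coords, frame = input$frame)
  kb_create_experiment(kb, input$modality, experiment_name,
                       metadata = list(format = input$format_name,
                                       symmetric = input$symmetric))
  ids <- as.character(coords$identifier)
  n <- length(ids)
  n_rel0 <- length(kb$rel_by_class[["measured brain connectivity"]])
  entries <- 0L
  add_cell <- function(i, j, v) {
    if (v == 0 && zero_policy == "drop") return(invisible(NULL))
    rel <- kb_relate(kb, "measured brain connectivity", refs[i], refs[j])
    kb_add_data_entry(kb, input$modality, experiment_name, rel,
                      input$format_name, v)
    entries <<- entries + 1L
  }
  if (input$symmetric) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      # canonical direction: ascending coordinate identifier
      if (ids[i] <= ids[j]) add_cell(i, j, input$values[i, j])
      else add_cell(j, i, input$values[i, j])
    }
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      add_cell(i, j, input$values[i, j])
    }
  }
  n_rel1 <- length(kb$rel_by_class[["measured brain connectivity"]])
  invisible(list(experiment = experiment_name,
                 relations_created = n_rel1 - n_rel0,
                 entries_created = entries,
                 coordinate_refs = refs))
}

#' Classify a functional connectivity value
#'
#' Bins partition [-1, 1] with the closed bounds as printed on lattice-graph
#' legends: CORRELATED for values >= 0.5, ANTICORRELATED for values < 0.0,
#' UNCORRELATED otherwise.
#'
#' @param value numeric vector of correlation values in [-1, 1].
#' @return Character vector of categories.
#' @export
classify_functional <- function(value) {
  if (any(is.na(value)) || any(value < -1) || any(value > 1))
    ckb_stop("functional connectivity values must lie in [-1, 1]",
             "ckb_validation_error")
  ifelse(value >= 0.5, "CORRELATED",
         ifelse(value < 0.0, "ANTICORRELATED", "UNCORRELATED"))
}

# modality values stored for one connectivity relation, as a named numeric
connection_values <- function(kb, rel, structural_method, functional_method) {
  c(structural = kb_entry_value(kb, structural_method, rel),
    functional = kb_entry_value(kb, functional_method, rel))
}

#' Extract a functional brain network template
#'
#' Returns exactly the measured-brain-connectivity relations whose both
#' endpoint coordinates resolve, via atlas parcellation and brain mapping,
#' to an ontology term within the is-a closure of \code{root_term}
#' (including the root itself). Each record carries origin/target labels,
#' coordinates, and the available structural and functional values.
#'
#' @param kb a knowledge base.
#' @param ontology ontology name.
#' @param root_term the ontology term defining the network (e.g. the limbic
#'   lobe); unresolvable roots are an error.
#' @param atlas optional atlas restriction for the parcellation step.
#' @param structural_method,functional_method experiment methods to pull
#'   values from.
#' @return data.frame of connection records: origin, target, coordinate
#'   ids/positions, structural, functional.
#' @export
extract_fbn <- function(kb, ontology, root_term, atlas = NULL,
                        structural_method = "DTI",
                        functional_method = "rs-fMRI") {
  terms <- ontology_descendants(kb, ontology, root_term, include_self = TRUE)
  rels <- kb_relations(kb, "measured brain connectivity")
  rows <- list()
  cache <- new.env(parent = emptyenv())
  in_set <- function(coord) {
    hit <- cache[[coord]]
    if (is.null(hit)) {
      hit <- any(coord_to_terms(kb, coord, ontology, atlas) %in% terms)
      cache[[coord]] <- hit
    }
    hit
  }
  for (rel in rels) {
    rec <- kb$relations[[rel]]
    if (!in_set(rec$source) || !in_set(rec$target)) next
    src <- kb$instances[[rec$source]]; tgt <- kb$instances[[rec$target]]
    sxyz <- coordinate_xyz(kb, rec$source)
    txyz <- coordinate_xyz(kb, rec$target)
    vals <- connection_values(kb, rel, structural_method, functional_method)
    rows[[length(rows) + 1L]] <- data.frame(
      origin = if (length(src$labels)) src$labels[1] else src$id,
      target = if (length(tgt$labels)) tgt$labels[1] else tgt$id,
      origin_id = src$id, target_id = tgt$id,
      origin_x = sxyz[1], origin_y = sxyz[2], origin_z = sxyz[3],
      target_x = txyz[1], target_y = txyz[2], target_z = txyz[3],
      structural = unname(vals["structural"]),
      functional = unname(vals["functional"]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(origin = character(), target = character(),
               origin_id = character(), target_id = character(),
               origin_x = numeric(), origin_y = numeric(), origin_z = numeric(),
               target_x = numeric(), target_y = numeric(), target_z = numeric(),
               structural = numeric(), functional = numeric(),
               stringsAsFactors = FALSE)
  out[order(out$origin_id, out$target_id), , drop = FALSE]
}

#' Pair counts of an FBN record set
#'
#' Connectivity is stored canonically (one directed relation per unordered
#' pair of coordinates), so the unordered count equals the record count and
#' the directed count doubles pairs between distinct coordinates.
#'
#' @param records output of \code{\link{extract_fbn}}.
#' @return list(unordered, directed).
#' @export
fbn_pair_counts <- function(records) {
  distinct <- sum(records$origin_id != records$target_id)
  list(unordered = nrow(records),
       directed = 2L * distinct + (nrow(records) - distinct))
}

#' Export connection records as a styled lattice graph
#'
#' Nodes are deduplicated by coordinate identifier and carry x, y, z (MNI
#' millimetres) and label attributes; edges carry width (the structural
#' value), color_value (functional connectivity or DEG average) and, for
#' functional coloring, color_category per the \code{\link{classify_functional}}
#' bins. Output ordering is stable, so re-export of the same records is
#' byte-identical.
#'
#' @param records data.frame with coordinate columns as produced by
#'   \code{\link{extract_fbn}} or \code{\link{crossmodal_join}}.
#' @param path output file.
#' @param edge_color_by "functional" or "deg".
#' @param format "graphml" or "json" (a node-link dialect with \code{nodes}
#'   and \code{links} arrays).
#' @return The path, invisibly.
#' @export
export_lattice <- function(records, path, edge_color_by = c("functional", "deg"),
                           format = c("graphml", "json")) {
  edge_color_by <- match.arg(edge_color_by)
  format <- match.arg(format)
  need <- c("origin_id", "target_id", "origin_x", "origin_y", "origin_z",
            "target_x", "target_y", "target_z")
  if (nrow(records) && (!all(need %in% names(records)) ||
                        anyNA(records[, need[3:8]])))
    ckb_stop("records must carry coordinates for lattice export",
             "ckb_data_error")
  nodes <- unique(rbind(
    data.frame(id = records$origin_id, label = records$origin,
               x = records$origin_x, y = records$origin_y,
               z = records$origin_z, stringsAsFactors = FALSE),
    data.frame(id = records$target_id, label = records$target,
               x = records$target_x, y = records$target_y,
               z = records$target_z, stringsAsFactors = FALSE)))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  cval <- if (edge_color_by == "functional") records$functional
          else records$deg_avg
  edges <- data.frame(from = records$origin_id, to = records$target_id,
                      width = records$structural,
                      color_value = cval, stringsAsFactors = FALSE)
  if (edge_color_by == "functional" && nrow(edges))
    edges$color_category <- classify_functional(edges$color_value)
  ord <- order(edges$from, edges$to, edges$color_value)
  edges <- edges[ord, , drop = FALSE]
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    jsonlite::write_json(
      list(nodes = nodes, links = edges),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
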