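# Independent brute-force oracles and random fixtures. The oracles avoid the
# package's indexes and traversal helpers on purpose: they rescan the raw
# stores so that engine results can be checked against naive enumeration.

# --- naive relation scan (no rel_by_source/rel_by_target indexes) ----------
oracle_neighbors <- function(kb, ref, label) {
  out <- character()
  for (cls in names(kb$classes)) {
    def <- kb$classes[[cls]]
    dir <- if (tolower(def$forward) == tolower(label)) "forward"
           else if (tolower(def$backward) == tolower(label)) "backward"
           else next
    for (r in ls(kb$relations)) {
      rec <- kb$relations[[r]]
      if (rec$class != cls) next
      if (dir == "forward" && rec$source == ref) out <- c(out, rec$target)
      if (dir == "backward" && rec$target == ref) out <- c(out, rec$source)
    }
  }
  out
}

oracle_check <- function(kb, ref, condition) {
  if (is.null(condition)) return(TRUE)
  k <- condition$kind
  if (k == "RELATED") {
    for (o in oracle_neighbors(kb, ref, condition$label))
      if (oracle_check(kb, o, condition$nested)) return(TRUE)
    return(FALSE)
  }
  if (k == "IN_CONTEXT") {
    for (ctx in ls(kb$contexts)) {
      id <- sub("^.*\x1f", "", ctx)
      if (id == condition$id && ref %in% kb$contexts[[ctx]]) return(TRUE)
    }
    return(FALSE)
  }
  if (k == "LABEL_IS") {
    rec <- kb$instances[[ref]]
    return(!is.null(rec) && tolower(condition$text) %in% tolower(rec$labels))
  }
  if (k == "ID_IS") {
    rec <- kb$instances[[ref]]
    return(!is.null(rec) && rec$id == condition$id)
  }
  if (k == "TYPE_IS") {
    rec <- kb$instances[[ref]]
    if (!is.null(rec)) return(rec$type == condition$type)
    return(kb$relations[[ref]]$class == condition$type)
  }
  if (k == "HAS_ENTRY") {
    for (key in ls(kb$entries)) {
      e <- kb$entries[[key]]
      if (e$method != condition$method || e$subject != ref) next
      v <- e$values[[condition$attr]]
      if (is.null(v)) next
      hit <- switch(condition$cmp,
                    "<" = v < condition$value, "<=" = v <= condition$value,
                    "=" = v == condition$value, ">=" = v >= condition$value,
                    ">" = v > condition$value, "!=" = v != condition$value)
      if (isTRUE(hit)) return(TRUE)
    }
    return(FALSE)
  }
  if (k == "AND") {
    for (ch in condition$children)
      if (!oracle_check(kb, ref, ch)) return(FALSE)
    return(TRUE)
  }
  if (k == "OR") {
    for (ch in condition$children)
      if (oracle_check(kb, ref, ch)) return(TRUE)
    return(FALSE)
  }
  if (k == "NOT") return(!oracle_check(kb, ref, condition$children[[1]]))
  stop("oracle: unknown condition kind ", k)
}

oracle_evaluate <- function(kb, query) {
  refs <- character()
  for (r in ls(kb$instances)) {
    rec <- kb$instances[[r]]
    if (rec$type == query$start_type && oracle_check(kb, r, query$condition))
      refs <- c(refs, rec$id)
  }
  sort(refs, method = "radix")
}

# --- recursive DFS over the raw children lists -----------------------------
oracle_descendants <- function(kb, ontology, term, include_self = FALSE) {
  children <- kb$ontologies[[ontology]]$children
  visit <- function(t) {
    out <- character()
    for (c in children[[t]]) out <- c(out, c, visit(c))
    out
  }
  out <- unique(visit(term))
  if (include_self) out <- unique(c(out, term))
  sort(out)
}

# --- random small knowledge bases for engine-vs-oracle equivalence ---------
LABEL_POOL <- c("alpha", "beta", "gamma", "delta")

random_small_kb <- function(seed) {
  set.seed(seed)
  kb <- kb_new()
  kb_define_object_type(kb, "A", "ELEMENT")
  kb_define_object_type(kb, "B", "ELEMENT")
  kb_define_object_type(kb, "C", "ELEMENT")
  kb_define_object_type(kb, "G", "CONTEXT")
  kb_define_relation_class(kb, "r1", "f1", "b1", list(c("A", "B")))
  kb_define_relation_class(kb, "r2", "f2", "b2", list(c("B", "C")))
  kb_define_relation_class(kb, "r3", "f3", "b3", list(c("A", "C"), c("A", "A")))
  kb_define_experiment_method(kb, "meas", "OBJECT_TYPE", "A",
                              list(format_def("score")))
  kb_create_experiment(kb, "meas", "e1")
  n_a <- sample(2:8, 1); n_b <- sample(1:6, 1); n_c <- sample(1:6, 1)
  a <- vapply(seq_len(n_a), function(i)
    kb_create_instance(kb, "A", paste0("a", i),
                       sample(LABEL_POOL, sample(0:2, 1))), "")
  b <- vapply(seq_len(n_b), function(i)
    kb_create_instance(kb, "B", paste0("b", i),
                       sample(LABEL_POOL, sample(0:2, 1))), "")
  c_ <- vapply(seq_len(n_c), function(i)
    kb_create_instance(kb, "C", paste0("c", i),
                       sample(LABEL_POOL, sample(0:2, 1))), "")
  g <- kb_create_instance(kb, "G", "grp1")
  for (m in sample(a, sample(0:n_a, 1))) kb_add_to_context(kb, g, m)
  n_rel <- sample(0:12, 1)
  for (k in seq_len(n_rel)) {
    cls <- sample(c("r1", "r2", "r3"), 1)
    if (cls == "r1") kb_relate(kb, "r1", sample(a, 1), sample(b, 1))
    else if (cls == "r2") kb_relate(kb, "r2", sample(b, 1), sample(c_, 1))
    else if (stats::runif(1) < 0.5) kb_relate(kb, "r3", sample(a, 1), sample(c_, 1))
    else kb_relate(kb, "r3", sample(a, 1), sample(a, 1))
  }
  for (m in sample(a, sample(0:min(3, n_a), 1)))
    kb_add_data_entry(kb, "meas", "e1", m, "score", stats::runif(1))
  kb
}

random_condition <- function(depth) {
  pick <- if (depth <= 0) sample(c("LABEL", "ID", "TYPE", "CTX", "ENTRY"), 1)
          else sample(c("REL", "AND", "OR", "NOT", "LABEL", "ID", "TYPE",
                        "CTX", "ENTRY"), 1)
  switch(pick,
    REL = q_related(sample(c("f1", "b1", "f2", "b2", "f3", "b3"), 1),
                    if (stats::runif(1) < 0.6) random_condition(depth - 1)),
    AND = do.call(q_and, lapply(seq_len(sample(1:2, 1)), function(i)
      random_condition(depth - 1))),
    OR = do.call(q_or, lapply(seq_len(sample(1:2, 1)), function(i)
      random_condition(depth - 1))),
    NOT = q_not(random_condition(depth - 1)),
    LABEL = q_label_is(sample(LABEL_POOL, 1)),
    ID = q_id_is(paste0(sample(c("a", "b", "c"), 1), sample(1:4, 1))),
    TYPE = q_type_is(sample(c("A", "B", "C"), 1)),
    CTX = q_in_context("grp1"),
    ENTRY = q_has_entry("meas", "value", sample(c("<", ">=", ">"), 1),
                        stats::runif(1)))
}

# engine vs oracle over n random kbs; returns number of agreements
count_oracle_agreements <- function(n_kbs, queries_per_kb = 3, seed0 = 1000) {
  agree <- 0L; total <- 0L
  for (k in seq_len(n_kbs)) {
    kb <- random_small_kb(seed0 + k)
    set.seed(seed0 + 100000 + k)
    for (q in seq_len(queries_per_kb)) {
      qry <- ckb_query(sample(c("A", "B", "C"), 1), random_condition(4))
      got <- kb_evaluate(kb, qry)$identifier
      want <- oracle_evaluate(kb, qry)
      total <- total + 1L
      if (identical(got, want)) agree <- agree + 1L
    }
  }
  list(agree = agree, total = total)
}

# --- tiny patient fixture ---------------------------------------------------
patient_fixture_kb <- function() {
  kb <- kb_new()
  kb_define_object_type(kb, "patient", "ELEMENT")
  kb_define_object_type(kb, "rs-fMRI scan", "EXPERIMENT")
  kb_define_object_type(kb, "DTI scan", "EXPERIMENT")
  kb_define_object_type(kb, "study", "CONTEXT")
  kb_define_relation_class(kb, "brain imaging", "is assessed by", "assesses",
    list(c("patient", "rs-fMRI scan"), c("patient", "DTI scan")))
  study <- kb_create_instance(kb, "study", "NKI Rockland")
  for (i in 1:5) kb_create_instance(kb, "patient", paste0("P", i))
  for (i in 1:4) kb_add_to_context(kb, study, ckb_ref("patient", paste0("P", i)))
  fmri <- vapply(1:3, function(i)
    kb_create_instance(kb, "rs-fMRI scan", paste0("F", i)), "")
  dti <- vapply(1:2, function(i)
    kb_create_instance(kb, "DTI scan", paste0("D", i)), "")
  # P1: both; P2: fMRI only; P3: DTI only; P4: both; P5 (outside study): both
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P1"), fmri[1])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P1"), dti[1])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P2"), fmri[2])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P3"), dti[2])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P4"), fmri[3])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P4"), dti[1])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P5"), fmri[1])
  kb_relate(kb, "brain imaging", ckb_ref("patient", "P5"), dti[1])
  kb
}

# --- small hand-built limbic-style kb for FBN / join tests -----------------
# four coordinates: three map to limbic sub-structures, one to a motor
# region; full functional connectivity, structural on a subset
limbic_fixture_kb <- function(deg_counts = NULL) {
  kb <- kb_new(brain_model = TRUE)
  kb_load_flat_atlas(kb, "atlasX", data.frame(
    entry_id = c("e1", "e2", "e3", "e4"),
    label = c("hippocampus", "amygdala", "cingulate", "precentral"),
    stringsAsFactors = FALSE))
  kb_load_ontology(kb, "ontoX",
    terms = data.frame(
      term_id = c("root", "limbic", "motor", "hip", "amy", "cin", "pre",
                  "hip_ca1", "hip_ca4"),
      name = c("brain", "limbic lobe", "motor area", "hippocampus",
               "amygdala", "cingulate", "precentral", "CA1", "CA4"),
      stringsAsFactors = FALSE),
    edges = data.frame(
      child_id = c("limbic", "motor", "hip", "amy", "cin", "pre",
                   "hip_ca1", "hip_ca4"),
      parent_id = c("root", "root", "limbic", "limbic", "limbic", "motor",
                    "hip", "hip"),
      stringsAsFactors = FALSE))
  structs <- c("hippocampus", "amygdala", "cingulate", "precentral",
               "CA1 field", "CA4 field")
  kb_add_brain_structures(kb, structs)
  coords <- data.frame(identifier = c("c1", "c2", "c3", "c4"),
                       x = c(-25, -22, -5, -40), y = c(-30, -5, 20, -10),
                       z = c(-8, -20, 30, 55),
                       label = c("hippocampus", "amygdala", "cingulate",
                                 "precentral"),
                       stringsAsFactors = FALSE)
  kb_add_coordinates(kb, coords)
  kb_parcellate_coordinates(kb, data.frame(
    coord_id = c("c1", "c2", "c3", "c4"),
    entry_id = c("e1", "e2", "e3", "e4"), stringsAsFactors = FALSE), "atlasX")
  kb_register_brain_mapping(kb, data.frame(
    atlas = c("atlasX", "atlasX", "atlasX", "atlasX", "", ""),
    entry_id = c("e1", "e2", "e3", "e4", NA, NA),
    structure_name = c("hippocampus", "amygdala", "cingulate", "precentral",
                       "CA1 field", "CA4 field"),
    ontology = c("ontoX", "ontoX", "ontoX", "ontoX", "ontoX", "ontoX"),
    term_id = c("hip", "amy", "cin", "pre", "hip_ca1", "hip_ca4"),
    stringsAsFactors = FALSE))
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- 0.6; S[1, 3] <- S[3, 1] <- 0.3
  S[2, 3] <- S[3, 2] <- 0.2; S[1, 4] <- S[4, 1] <- 0.5
  F <- matrix(0, 4, 4)
  F[1, 2] <- F[2, 1] <- 0.7; F[1, 3] <- F[3, 1] <- 0.55
  F[2, 3] <- F[3, 2] <- -0.1; F[1, 4] <- F[4, 1] <- 0.4
  F[2, 4] <- F[4, 2] <- 0.1; F[3, 4] <- F[4, 3] <- 0.2
  ci_s <- connectivity_input(S, coords$label,
                             coords[, c("identifier", "x", "y", "z")],
                             "DTI", "normalized fiber density")
  ci_f <- connectivity_input(F, coords$label,
                             coords[, c("identifier", "x", "y", "z")],
                             "rs-fMRI", "normalized correlation value")
  import_connectivity_matrix(kb, ci_s, "dti avg")
  import_connectivity_matrix(kb, ci_f, "fc avg")
  if (!is.null(deg_counts)) import_deg(kb, deg_counts)
  kb
}
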