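expr_fixture <- function() {
  data.frame(
    donor = "9861",
    structure_id = c("CA4", "CA4", "CA4", "putamen", "putamen"),
    probe_id = c("p1", "p2", "p3", "p1", "p4"),
    gene_symbol = c("fkbp5", "fkbp5", "gmeb1;gmeb2", "fkbp5", "actb"),
    expression = c(9.1, 7.2, 8.4, 6.0, 11.0),
    pacall = c(1, 1, 0, 1, 1),
    stringsAsFactors = FALSE)
}

test_that("expression import groups experiments by donor and location", {
  kb <- kb_new(brain_model = TRUE)
  out <- import_expression(kb, expr_fixture())
  expect_equal(out$experiments, 2L)
  expect_equal(out$entries, 5L)
  # a probe with two gene symbols binds both genes
  probes_g1 <- kb_neighbors(kb, ckb_ref("DNA", "gmeb1"), "is detected by")
  probes_g2 <- kb_neighbors(kb, ckb_ref("DNA", "gmeb2"), "is detected by")
  expect_equal(sub("^.*\x1f", "", probes_g1), "p3")
  expect_equal(probes_g1, probes_g2)
  # backward label works too
  expect_setequal(sub("^.*\x1f", "", kb_neighbors(
    kb, ckb_ref("probe", "p3"), "binds to")), c("gmeb1", "gmeb2"))
  bad <- expr_fixture(); bad$pacall[1] <- 2
  expect_error(import_expression(kb_new(brain_model = TRUE), bad),
               class = "ckb_data_error")
})

test_that("gene-filtered expression only surfaces probes bound to the gene", {
  kb <- kb_new(brain_model = TRUE)
  import_expression(kb, expr_fixture())
  rec <- localized_expression(kb, "fkbp5", min_value = 0,
                              require_pacall = FALSE)
  expect_setequal(rec$probe, c("p1", "p2"))  # never p3/p4 (other genes)
  expect_equal(nrow(rec), 3L)                # p1 at two locations
  expect_error(localized_expression(kb, "nosuchgene"),
               class = "ckb_lookup_error")
})

test_that("localized expression applies the strict value and PACall filters", {
  tab <- data.frame(
    donor = "d1", structure_id = paste0("s", 1:4),
    probe_id = paste0("q", 1:4), gene_symbol = "fkbp5",
    expression = c(7.9, 8.0, 8.1, 9.0), pacall = c(1, 1, 0, 1),
    stringsAsFactors = FALSE)
  kb <- kb_new(brain_model = TRUE)
  import_expression(kb, tab)
  hits <- localized_expression(kb, "fkbp5")
  expect_equal(hits$value, 9.0)  # 7.9/8.0 fail strict >8; 8.1 fails PACall
  relaxed <- localized_expression(kb, "fkbp5", require_pacall = FALSE)
  expect_equal(relaxed$value, c(9.0, 8.1))  # sorted descending
  tab0 <- tab; tab0$pacall <- 0
  kb0 <- kb_new(brain_model = TRUE)
  import_expression(kb0, tab0)
  expect_equal(nrow(localized_expression(kb0, "fkbp5")), 0L)
})

test_that("DEG links are unordered, conflict-checked and non-negative", {
  kb <- kb_new(brain_model = TRUE)
  kb_add_brain_structures(kb, c("s1", "s2", "s3"))
  n <- import_deg(kb, data.frame(structure_a = c("s1", "s1"),
                                 structure_b = c("s2", "s3"),
                                 deg_count = c(10, 20)))
  expect_equal(n, 2L)
  expect_equal(kb_deg_count(kb, "s2", "s1"), 10)  # symmetric lookup
  expect_equal(kb_deg_count(kb, "s1", "s3"), 20)
  expect_true(is.na(kb_deg_count(kb, "s2", "s3")))
  # re-import with the same value is idempotent; a conflict refuses
  expect_silent(import_deg(kb, data.frame(structure_a = "s2",
                                          structure_b = "s1",
                                          deg_count = 10)))
  expect_error(import_deg(kb, data.frame(structure_a = "s2",
                                         structure_b = "s1",
                                         deg_count = 11)),
               class = "ckb_data_error")
  expect_error(import_deg(kb, data.frame(structure_a = "s1",
                                         structure_b = "s2",
                                         deg_count = -1)),
               class = "ckb_data_error")
})

test_that("the cross-modal join averages DEG over descendant structure pairs", {
  # DEG known only between hippocampal subfields and the amygdala: without
  # ontology descent the join is empty; with descent the hippocampus-
  # amygdala connection averages its two subfield links
  deg <- data.frame(structure_a = c("CA1 field", "CA4 field"),
                    structure_b = c("amygdala", "amygdala"),
                    deg_count = c(10, 20))
  kb <- limbic_fixture_kb(deg_counts = deg)
  flat <- crossmodal_join(kb, ontology = "ontoX", descend = FALSE)
  expect_equal(nrow(flat), 0L)
  rec <- crossmodal_join(kb, ontology = "ontoX")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$origin_id, "c1")
  expect_equal(rec$target_id, "c2")
  expect_equal(rec$deg_avg, 15)
  expect_equal(rec$n_subpairs, 2L)
  expect_equal(rec$structural, 0.6)
  expect_equal(rec$functional, 0.7)
})

test_that("connections without a mapping chain are skipped with a warning", {
  deg <- data.frame(structure_a = "CA1 field", structure_b = "amygdala",
                    deg_count = 5)
  kb <- limbic_fixture_kb(deg_counts = deg)
  # an extra coordinate with connectivity but no parcellation
  refs <- kb_add_coordinates(kb, data.frame(identifier = "c9", x = 9, y = 9,
                                            z = 9))
  conn <- kb_relate(kb, "measured brain connectivity",
                    ckb_ref("measured brain coordinates", "c1"), refs[1])
  kb_add_data_entry(kb, "rs-fMRI", "fc avg", conn,
                    "normalized correlation value", 0.9)
  expect_warning(rec <- crossmodal_join(kb, ontology = "ontoX"),
                 "skipped")
  expect_equal(attr(rec, "skipped"), 1L)
  expect_equal(nrow(rec), 1L)  # the resolvable c1-c2 connection remains
})

test_that("the join equals a naive nested-loop join on a synthetic kb", {
  kb <- generate_kb(synth_config(n_regions = 6, seed = 31))
  got <- crossmodal_join(kb, ontology = "synthonto")
  # brute force from the raw stores, using only full scans and the
  # recursive-DFS descendants oracle
  scan_targets <- function(ref, class) {
    out <- character()
    for (r in ls(kb$relations)) {
      rec <- kb$relations[[r]]
      if (rec$class == class && rec$source == ref)
        out <- c(out, rec$target)
    }
    out
  }
  rows <- list()
  for (r in ls(kb$relations)) {
    rec <- kb$relations[[r]]
    if (rec$class != "measured brain connectivity") next
    side <- function(coord) {
      structs <- character()
      for (e in scan_targets(coord, "image parcellation"))
        for (s in scan_targets(e, "brain mapping"))
          for (t in scan_targets(s, "brain mapping")) {
            terms <- oracle_descendants(kb, "synthonto",
                                        sub("^.*\x1f", "", t),
                                        include_self = TRUE)
            for (rr in ls(kb$relations)) {
              m <- kb$relations[[rr]]
              if (m$class == "brain mapping" &&
                  sub("\x1f.*$", "", m$target) == "synthonto" &&
                  sub("^.*\x1f", "", m$target) %in% terms)
                structs <- c(structs, sub("^.*\x1f", "", m$source))
            }
          }
      unique(structs)
    }
    o <- side(rec$source); t <- side(rec$target)
    if (!length(o) || !length(t)) next
    counts <- c(); seen <- character()
    for (a in o) for (b in t) {
      key <- paste(sort(c(a, b)), collapse = "\x1f")
      if (key %in% seen) next
      seen <- c(seen, key)
      cnt <- kb_deg_count(kb, a, b)
      if (!is.na(cnt)) counts <- c(counts, cnt)
    }
    if (!length(counts)) next
    rows[[length(rows) + 1L]] <- data.frame(
      origin_id = sub("^.*\x1f", "", rec$source),
      target_id = sub("^.*\x1f", "", rec$target),
      deg_avg = mean(counts), n_subpairs = length(counts),
      stringsAsFactors = FALSE)
  }
  want <- do.call(rbind, rows)
  want <- want[order(want$origin_id, want$target_id), ]
  expect_equal(got$origin_id, want$origin_id)
  expect_equal(got$target_id, want$target_id)
  expect_equal(got$deg_avg, want$deg_avg)
  expect_equal(got$n_subpairs, want$n_subpairs)
  # the average always lies within the contributing counts' range
  expect_true(all(got$deg_avg >= 0))
})

test_that("connection filtering follows the printed inequalities", {
  rec <- paper_tables_fixture()
  expect_identical(filter_connections(rec), rec)  # no thresholds: identity
  nine <- filter_connections(rec, min_struct = 0.5, min_func = 0.5,
                             max_deg = 10)
  expect_equal(nrow(nine), 9L)
  expect_true(all(nine$table == 3))
  # functional >= 0.5 with DEG > 200 recovers exactly the table-2 rows
  strong_deg <- filter_connections(rec, min_func = 0.5, min_deg = 200)
  expect_equal(nrow(strong_deg), 8L)
  expect_true(all(strong_deg$table == 2))
  # bounds are inclusive for >= / <= and strict for min_deg
  edge <- data.frame(structural = c(0.5, 0.4999), functional = c(0.5, 0.5),
                     deg_avg = c(10, 200))
  expect_equal(nrow(filter_connections(edge, min_struct = 0.5)), 1L)
  expect_equal(nrow(filter_connections(edge, max_deg = 10)), 1L)
  expect_equal(nrow(filter_connections(edge, min_deg = 200)), 0L)
  # records lacking a filtered field fail that filter
  nas <- data.frame(structural = c(NA, 0.9), functional = 0.9,
                    deg_avg = c(5, NA))
  expect_equal(nrow(filter_connections(nas, min_struct = 0.1)), 1L)
  expect_equal(nrow(filter_connections(nas, max_deg = 10)), 1L)
  expect_equal(nrow(filter_connections(nas, min_struct = 0.1,
                                       max_deg = 10)), 0L)
  # out-of-range thresholds refuse
  expect_error(filter_connections(rec, min_struct = 2),
               class = "ckb_validation_error")
  expect_error(filter_connections(rec, min_func = -3),
               class = "ckb_validation_error")
})

test_that("tightening any threshold never enlarges the filtered set", {
  set.seed(77)
  rec <- data.frame(structural = stats::runif(120),
                    functional = stats::runif(120, -1, 1),
                    deg_avg = stats::rlnorm(120, 3, 1.5))
  for (k in 1:50) {
    ms <- stats::runif(1); mf <- stats::runif(1, -1, 1)
    md <- stats::runif(1, 0, 500)
    loose <- nrow(filter_connections(rec, min_struct = ms, min_func = mf,
                                     max_deg = md))
    tighter <- nrow(filter_connections(rec, min_struct = min(ms + 0.1, 1),
                                       min_func = min(mf + 0.1, 1),
                                       max_deg = max(md - 50, 0)))
    expect_lte(tighter, loose)
  }
})
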