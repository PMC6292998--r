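coords3 <- data.frame(identifier = c("c1", "c2", "c3"),
                      x = c(1, 2, 3), y = 0, z = 0)

test_that("symmetric import stores one canonical relation per unordered pair", {
  kb <- kb_new(brain_model = TRUE)
  M <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3)
  ci <- connectivity_input(M, c("r1", "r2", "r3"), coords3, "rs-fMRI",
                          "normalized correlation value")
  expect_true(ci$symmetric)
  out <- import_connectivity_matrix(kb, ci, "avg")
  expect_equal(out$relations_created, 3L)
  expect_equal(out$entries_created, 3L)
  # canonical direction: ascending coordinate identifier
  for (r in kb_relations(kb, "measured brain connectivity")) {
    rec <- kb_relation(kb, r)
    expect_true(sub("^.*\x1f", "", rec$source) < sub("^.*\x1f", "", rec$target))
  }
})

test_that("asymmetric matrices keep one relation per ordered pair", {
  kb <- kb_new(brain_model = TRUE)
  M <- matrix(c(0, .2, .3, .25, 0, .4, .35, .45, 0), 3, 3)
  ci <- connectivity_input(M, c("r1", "r2", "r3"), coords3, "rs-fMRI",
                          "normalized correlation value", symmetric = FALSE)
  out <- import_connectivity_matrix(kb, ci, "avg")
  expect_equal(out$relations_created, 6L)
  expect_equal(out$entries_created, 6L)
  # declaring a non-symmetric matrix symmetric is rejected
  expect_error(connectivity_input(M, c("r1", "r2", "r3"), coords3, "rs-fMRI",
                                  "normalized correlation value",
                                  symmetric = TRUE),
               class = "ckb_data_error")
})

test_that("a second modality shares relations and only adds entries", {
  kb <- kb_new(brain_model = TRUE)
  Mf <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3)
  Ms <- matrix(c(0, .5, .6, .5, 0, .7, .6, .7, 0), 3, 3)
  import_connectivity_matrix(kb, connectivity_input(
    Mf, c("r1", "r2", "r3"), coords3, "rs-fMRI",
    "normalized correlation value"), "avg")
  out2 <- import_connectivity_matrix(kb, connectivity_input(
    Ms, c("r1", "r2", "r3"), coords3, "DTI", "normalized fiber density"),
    "avg")
  expect_equal(out2$relations_created, 0L)
  expect_equal(out2$entries_created, 3L)
})

test_that("zero cells follow the zero policy; diagonals are always dropped", {
  kb <- kb_new(brain_model = TRUE)
  M <- matrix(c(0, 0, .3, 0, 0, 0, .3, 0, 0), 3, 3)
  # structural default: zeros mean no tract and are dropped
  out <- import_connectivity_matrix(kb, connectivity_input(
    M, c("r1", "r2", "r3"), coords3, "DTI", "normalized fiber density"),
    "avg")
  expect_equal(out$entries_created, 1L)
  # functional default: zero correlation is informative and kept
  kb2 <- kb_new(brain_model = TRUE)
  out2 <- import_connectivity_matrix(kb2, connectivity_input(
    M, c("r1", "r2", "r3"), coords3, "rs-fMRI",
    "normalized correlation value"), "avg")
  expect_equal(out2$entries_created, 3L)
})

test_that("import is invariant under row/column permutation", {
  base <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3)
  perm <- c(3, 1, 2)
  kb1 <- kb_new(brain_model = TRUE)
  import_connectivity_matrix(kb1, connectivity_input(
    base, c("r1", "r2", "r3"), coords3, "rs-fMRI",
    "normalized correlation value"), "avg")
  kb2 <- kb_new(brain_model = TRUE)
  import_connectivity_matrix(kb2, connectivity_input(
    base[perm, perm], c("r1", "r2", "r3")[perm], coords3[perm, ], "rs-fMRI",
    "normalized correlation value"), "avg")
  expect_identical(kb_save(kb1), kb_save(kb2))
})

test_that("matrix and region files round trip through the reader", {
  mfile <- withr::local_tempfile(fileext = ".txt")
  rfile <- withr::local_tempfile(fileext = ".txt")
  M <- matrix(c(0, .21, .21, 0), 2, 2)
  write(t(M), mfile, ncolumns = 2)
  writeLines(c("left putamen -25 0 2", "right putamen 27 1 0"), rfile)
  ci <- read_connectivity_matrix(mfile, rfile, "rs-fMRI",
                                 "normalized correlation value")
  expect_equal(ci$values, M)
  expect_equal(ci$labels, c("left putamen", "right putamen"))
  expect_true(ci$symmetric)
})

test_that("functional classification uses the printed closed bins", {
  expect_equal(classify_functional(0.73615919), "CORRELATED")
  expect_equal(classify_functional(-0.01262453), "ANTICORRELATED")
  expect_equal(classify_functional(0.020203011), "UNCORRELATED")
  expect_equal(classify_functional(0.5), "CORRELATED")      # closed bound
  expect_equal(classify_functional(0.0), "UNCORRELATED")
  expect_error(classify_functional(1.2), class = "ckb_validation_error")
  # the three bins partition [-1, 1]
  set.seed(5)
  vals <- c(stats::runif(500, -1, 1), -1, 1, 0, 0.5)
  cats <- classify_functional(vals)
  expect_true(all(cats %in% c("CORRELATED", "UNCORRELATED",
                              "ANTICORRELATED")))
  expect_equal(cats, ifelse(vals >= 0.5, "CORRELATED",
                            ifelse(vals < 0, "ANTICORRELATED",
                                   "UNCORRELATED")))
})

test_that("FBN extraction keeps exactly the connections inside the term closure", {
  kb <- limbic_fixture_kb()
  rec <- extract_fbn(kb, "ontoX", "limbic", atlas = "atlasX")
  expect_equal(nrow(rec), 3L)  # c1-c2, c1-c3, c2-c3; c4's edges excluded
  expect_setequal(paste(rec$origin_id, rec$target_id),
                  c("c1 c2", "c1 c3", "c2 c3"))
  expect_equal(rec$structural[rec$origin_id == "c1" & rec$target_id == "c2"],
               0.6)
  expect_equal(rec$functional[rec$origin_id == "c2" & rec$target_id == "c3"],
               -0.1)
  # ontology monotonicity: a sub-term's network nests inside its ancestor's
  hip_only <- extract_fbn(kb, "ontoX", "hip", atlas = "atlasX")
  expect_true(all(paste(hip_only$origin_id, hip_only$target_id) %in%
                    paste(rec$origin_id, rec$target_id)))
  whole <- extract_fbn(kb, "ontoX", "root", atlas = "atlasX")
  expect_true(all(paste(rec$origin_id, rec$target_id) %in%
                    paste(whole$origin_id, whole$target_id)))
  expect_equal(nrow(whole), 6L)
  # term with no mapped structures
  expect_equal(nrow(extract_fbn(kb, "ontoX", "hip_ca1", atlas = "atlasX")), 0L)
  expect_error(extract_fbn(kb, "ontoX", "no term"),
               class = "ckb_lookup_error")
  counts <- fbn_pair_counts(rec)
  expect_equal(counts$unordered, 3L)
  expect_equal(counts$directed, 6L)
})

test_that("lattice export is well-formed, styled and byte-stable", {
  kb <- limbic_fixture_kb()
  rec <- extract_fbn(kb, "ontoX", "limbic", atlas = "atlasX")
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_lattice(rec, f1)
  export_lattice(rec, f2)
  expect_identical(readLines(f1), readLines(f2))
  g <- igraph::read_graph(f1, format = "graphml")
  expect_lte(igraph::vcount(g), 6L)
  expect_equal(igraph::ecount(g), 3L)
  expect_true(all(c("label", "x", "y", "z") %in%
                    igraph::vertex_attr_names(g)))
  expect_true(all(c("width", "color_value", "color_category") %in%
                    igraph::edge_attr_names(g)))
  expect_equal(sort(igraph::E(g)$color_category),
               sort(classify_functional(rec$functional)))
  # empty record sets still produce a parseable document
  f3 <- withr::local_tempfile(fileext = ".graphml")
  export_lattice(rec[0, ], f3)
  g0 <- igraph::read_graph(f3, format = "graphml")
  expect_equal(igraph::vcount(g0), 0L)
  # json node-link dialect
  f4 <- withr::local_tempfile(fileext = ".json")
  export_lattice(rec, f4, format = "json")
  doc <- jsonlite::fromJSON(f4)
  expect_equal(nrow(doc$nodes), 3L)
  expect_equal(nrow(doc$links), 3L)
})
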