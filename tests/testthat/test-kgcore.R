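test_that("object types derive from the closed kind set with unique names", {
  kb <- kb_new()
  def <- kb_define_object_type(kb, "patient", "ELEMENT")
  expect_equal(def$kind, "ELEMENT")
  onto <- kb_define_object_type(kb, "FMA", "ONTOLOGY")
  expect_equal(onto$kind, "ONTOLOGY")
  expect_error(kb_define_object_type(kb, "patient", "ELEMENT"),
               class = "ckb_definition_error")
  expect_error(kb_define_object_type(kb, "thing", "GADGET"))
})

test_that("relation classes need distinct, globally resolvable labels and known pairs", {
  kb <- kb_new()
  kb_define_object_type(kb, "patient", "ELEMENT")
  kb_define_object_type(kb, "rs-fMRI scan", "EXPERIMENT")
  kb_define_object_type(kb, "DTI scan", "EXPERIMENT")
  kb_define_relation_class(kb, "brain imaging", "is assessed by", "assesses",
    list(c("patient", "rs-fMRI scan"), c("patient", "DTI scan")))
  fwd <- kb_resolve_label(kb, "is assessed by")
  bwd <- kb_resolve_label(kb, "ASSESSES")  # case-insensitive
  expect_equal(fwd, list(class = "brain imaging", direction = "forward"))
  expect_equal(bwd$direction, "backward")
  expect_error(kb_define_relation_class(kb, "selfsame", "looks at", "looks at",
                                        list(c("patient", "patient"))),
               class = "ckb_definition_error")
  expect_error(kb_define_relation_class(kb, "broken", "x", "y",
                                        list(c("patient", "nonexistent"))),
               class = "ckb_definition_error")
  # reusing an existing label elsewhere would make traversal ambiguous
  expect_error(kb_define_relation_class(kb, "other", "is assessed by", "z",
                                        list(c("patient", "patient"))),
               class = "ckb_definition_error")
})

test_that("instances are keyed by (type, identifier) and round trip", {
  kb <- kb_new(brain_model = TRUE)
  kb_create_instance(kb, "patient", "P1")
  expect_equal(kb_instance(kb, "patient", "P1")$id, "P1")
  expect_error(kb_create_instance(kb, "patient", "P1"),
               class = "ckb_definition_error")
  expect_error(kb_create_instance(kb, "patientt", "P2"),
               class = "ckb_definition_error")
  # a Craddock-style coordinate file: 188 rows -> 188 retrievable objects
  coords <- data.frame(identifier = sprintf("cc%03d", 1:188),
                       x = seq(-70, 70, length.out = 188),
                       y = 0, z = 10)
  kb_add_coordinates(kb, coords)
  expect_length(kb_instances(kb, "measured brain coordinates"), 188)
  expect_true(kb_has_instance(kb, "measured brain coordinates", "cc100"))
})

test_that("relate is idempotent, directed, and validates endpoint pairs", {
  kb <- patient_fixture_kb()
  p1 <- ckb_ref("patient", "P1")
  f1 <- ckb_ref("rs-fMRI scan", "F1")
  r1 <- kb_relate(kb, "brain imaging", p1, f1)
  r2 <- kb_relate(kb, "brain imaging", p1, f1)
  expect_identical(r1, r2)
  # backward traversal from the scan recovers the patients (involution on
  # the fixture's shared scan F1)
  back <- kb_neighbors(kb, f1, "assesses")
  expect_setequal(back, c(p1, ckb_ref("patient", "P5")))
  for (src in back)
    expect_true(f1 %in% kb_neighbors(kb, src, "is assessed by"))
  expect_error(kb_relate(kb, "brain imaging", f1, p1),
               class = "ckb_relation_error")
})

test_that("annotations validate kinds and declared ranges and are queryable", {
  kb <- kb_new()
  kb_define_object_type(kb, "processing step", "ELEMENT")
  kb_define_annotation_schema(kb, "BET parameters", list(
    list(name = "fractional intensity threshold", kind = "real",
         range = c(0, 1))))
  kb_attach_schema(kb, "processing step", "BET parameters")
  bet <- kb_create_instance(kb, "processing step", "BET")
  kb_annotate(kb, bet, "BET parameters",
              list("fractional intensity threshold" = 0.5))
  expect_error(kb_annotate(kb, bet, "BET parameters",
                           list("fractional intensity threshold" = 1.5)),
               class = "ckb_validation_error")
  hits <- kb_evaluate(kb, ckb_query("processing step",
    q_has_annotation("BET parameters", "fractional intensity threshold",
                     "=", 0.5)))
  expect_equal(hits$identifier, "BET")
  # schema not attached to the type -> refuse
  kb_define_annotation_schema(kb, "unrelated", list())
  expect_error(kb_annotate(kb, bet, "unrelated", list()),
               class = "ckb_validation_error")
})

test_that("annotation schemas reject duplicate attributes and allow empty ones", {
  kb <- kb_new()
  expect_silent(kb_define_annotation_schema(kb, "empty", list()))
  expect_error(kb_define_annotation_schema(kb, "dup", list(
    list(name = "a", kind = "real"), list(name = "a", kind = "text"))),
    class = "ckb_definition_error")
})

test_that("contexts group instances idempotently and only CONTEXT kinds accept members", {
  kb <- patient_fixture_kb()
  study <- ckb_ref("study", "NKI Rockland")
  p1 <- ckb_ref("patient", "P1")
  kb_add_to_context(kb, study, p1)  # already a member: no duplicate
  expect_equal(sum(kb_context_members(kb, study) == p1), 1L)
  expect_length(kb_context_members(kb, study), 4L)
  expect_error(kb_add_to_context(kb, p1, ckb_ref("patient", "P2")),
               class = "ckb_validation_error")
})

test_that("relation sources may be relations; targets must be instances", {
  kb <- kb_new(brain_model = TRUE)
  coords <- data.frame(identifier = c("k1", "k2"), x = 0:1, y = 0, z = 0)
  refs <- kb_add_coordinates(kb, coords)
  conn <- kb_relate(kb, "measured brain connectivity", refs[1], refs[2])
  kb_define_object_type(kb, "note", "ELEMENT")
  kb_define_relation_class(kb, "connection note", "is noted in", "notes",
    list(c("measured brain connectivity", "note")))
  note <- kb_create_instance(kb, "note", "n1")
  rel <- kb_relate(kb, "connection note", conn, note)
  expect_equal(kb_relation(kb, rel)$source, conn)
  expect_error(kb_relate(kb, "connection note", note, conn),
               class = "ckb_relation_error")
})

test_that("serialization round trips the full object/relation/annotation sets", {
  kb <- patient_fixture_kb()
  kb_define_annotation_schema(kb, "meta", list(
    list(name = "quality", kind = "enumeration", levels = c("good", "bad"))))
  kb_attach_schema(kb, "patient", "meta")
  kb_annotate(kb, ckb_ref("patient", "P2"), "meta", list(quality = "good"))
  kb_define_experiment_method(kb, "laboratory", "OBJECT_TYPE", "patient",
                              list(format_def("score")))
  kb_create_experiment(kb, "laboratory", "visit1", list(protocol = "v1"))
  kb_add_data_entry(kb, "laboratory", "visit1", ckb_ref("patient", "P1"),
                    "score", 3.25)
  json1 <- kb_save(kb)
  kb2 <- kb_load(json1)
  json2 <- kb_save(kb2)
  expect_identical(json1, json2)
  # counts conserved, no silent duplication
  expect_equal(length(ls(kb2$instances)), length(ls(kb$instances)))
  expect_equal(length(ls(kb2$relations)), length(ls(kb$relations)))
  expect_equal(kb_entry_value(kb2, "laboratory", ckb_ref("patient", "P1")),
               3.25)
  expect_equal(kb_instance(kb2, "patient", "P2")$ann[[1]]$values$quality,
               "good")
})

test_that("every stored relation respects its class's allowed pairs (audit)", {
  for (seed in c(11, 12, 13)) {
    kb <- random_small_kb(seed)
    expect_true(kb_audit(kb))
  }
})
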