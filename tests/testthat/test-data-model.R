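test_that("canonical corpus round-trips and maps gold labels to pair polarity", {
  doc <- tiny_document("1:CID:2")
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(list(doc), path)
  docs <- read_corpus(path, "canonical", schema_cdr())
  expect_length(docs, 1L)
  expect_equal(docs[[1L]]$doc_id, "d1")
  expect_length(docs[[1L]]$entities, 2L)

  pairs <- enumerate_candidate_pairs(docs[[1L]], schema_cdr(), "all_pairs")
  expect_length(pairs, 1L)
  expect_equal(pairs[[1L]]$gold, "positive")

  # the no-relation label code makes the same pair negative
  neg <- tiny_document("1:NR:2")
  neg_pairs <- enumerate_candidate_pairs(neg, schema_cdr(), "all_pairs")
  expect_equal(neg_pairs[[1L]]$gold, "negative")
})

test_that("canonical round-trip reproduces documents field-for-field", {
  suite <- standard_suite()
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(suite$documents, path)
  back <- read_corpus(path, "canonical", suite$schema)
  expect_equal(length(back), length(suite$documents))
  for (i in seq_along(back)) {
    expect_equal(unclass(back[[i]]), unclass(suite$documents[[i]]))
  }
})

test_that("docred-style records convert with per-cluster mentions and char spans", {
  rec <- list(list(
    title = "Sample abstract",
    doc_id = "dr1",
    sents = list(list("Lidocaine", "was", "given", "."),
                 list("Lidocaine", "caused", "severe", "seizures", ".")),
    vertexSet = list(
      list(list(name = "Lidocaine", sent_id = 0L, pos = list(0L, 1L),
                type = "chemical", id = "MESH:D008012"),
           list(name = "Lidocaine", sent_id = 1L, pos = list(0L, 1L),
                type = "chemical")),
      list(list(name = "severe seizures", sent_id = 1L, pos = list(2L, 4L),
                type = "disease", id = "MESH:D012640"))),
    labels = list(list(h = 0L, t = 1L, r = "1:CID:2"))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE)

  docs <- read_corpus(path, "docred_json", schema_cdr())
  d <- docs[[1L]]
  # hand-converted expectations
  expect_equal(d$passages, c("Lidocaine was given .",
                             "Lidocaine caused severe seizures ."))
  ent1 <- d$entities[[1L]]
  expect_equal(ent1$entity_id, "MESH:D008012")
  expect_length(ent1$mentions, 2L)
  expect_equal(ent1$mentions[[1L]]$start, 0L)
  expect_equal(ent1$mentions[[1L]]$end, 9L)
  ent2 <- d$entities[[2L]]
  m <- ent2$mentions[[1L]]
  expect_equal(substr(d$passages[[2L]], m$start + 1L, m$end), "severe seizures")
  expect_equal(d$gold_labels,
               data.frame(head = "MESH:D008012", tail = "MESH:D012640",
                          label = "1:CID:2", stringsAsFactors = FALSE))
})

test_that("pair-list corpora fold rows into annotated documents", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("doc_id\ttext\thead\ttail\tlabel",
               "a1\tAspirin caused bleeding and nausea.\tAspirin\tbleeding\tDrug-ADE",
               "a1\tAspirin caused bleeding and nausea.\tAspirin\tnausea\tDrug-ADE"),
             path)
  docs <- read_corpus(path, "pair_list", schema_ade())
  expect_length(docs, 1L)
  pairs <- enumerate_candidate_pairs(docs[[1L]], schema_ade(), "annotated_only")
  expect_length(pairs, 2L)
  expect_true(all(vapply(pairs, function(p) p$gold, character(1)) == "positive"))
})

test_that("all-pairs enumeration is the typed cartesian product", {
  doc <- multi_pair_document(2L, 3L, positives = list(c("c1", "d1")))
  pairs <- enumerate_candidate_pairs(doc, schema_cdr(), "all_pairs")
  expect_length(pairs, 6L)
  gold <- vapply(pairs, function(p) p$gold, character(1))
  expect_equal(sum(gold == "positive"), 1L)
  pos <- pairs[[which(gold == "positive")]]
  expect_equal(c(pos$head$entity_id, pos$tail$entity_id), c("c1", "d1"))

  # |heads| x |tails| for several shapes, including a missing required type
  for (shape in list(c(1L, 1L), c(3L, 2L), c(2L, 4L))) {
    d <- multi_pair_document(shape[[1L]], shape[[2L]])
    expect_length(enumerate_candidate_pairs(d, schema_cdr(), "all_pairs"),
                  shape[[1L]] * shape[[2L]])
  }
  no_disease <- document("e1", "t", "Drug chemonly was administered.",
                         list(tiny_entity("c1", "chemical", "chemonly",
                                          "Drug chemonly was administered.")))
  expect_length(enumerate_candidate_pairs(no_disease, schema_cdr(), "all_pairs"), 0L)
})

test_that("malformed records and unknown label codes raise informative errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"doc_id":"x1","title":"t","passages":["ab"]}]', path)
  expect_error(read_corpus(path, "canonical", schema_cdr()),
               "record 1.*entities")

  bad_label <- '[{"doc_id":"x1","title":"t","passages":["abcd"],
    "entities":[{"entity_id":"c1","type":"chemical",
      "mentions":[{"surface":"ab","start":0,"end":2,"passage_index":0}]},
      {"entity_id":"d1","type":"disease",
      "mentions":[{"surface":"cd","start":2,"end":4,"passage_index":0}]}],
    "gold_labels":[{"head":"c1","tail":"d1","label":"1:XXX:2"}]}]'
  writeLines(bad_label, path)
  expect_error(read_corpus(path, "canonical", schema_cdr()), "1:XXX:2")

  expect_error(document("z", "t", "ab",
                        list(entity("c1", "chemical",
                                    list(entity_mention("abc", 0, 3)))),
                        schema = schema_cdr()),
               "exceeds passage length")
  expect_error(document("z", "t", "ab", list(),
                        data.frame(head = "c1", tail = "d1", label = "1:CID:2")),
               "undeclared")
})

test_that("schema and mention invariants are enforced", {
  expect_error(relation_schema("X", "a", "b", "POS", "POS", "{head} {tail}?"),
               "must differ")
  expect_error(relation_schema("X", "a", "b", "POS", "NEG", "{head} only?"),
               "exactly one")
  expect_error(entity_mention("x", 3, 3), "start < end")
  expect_error(entity("e", "t", list()), "at least one mention")
})
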