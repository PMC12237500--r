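test_that("the fallback encoder is deterministic, unit-norm and discriminative", {
  enc <- hash_encoder(dim = 64L)
  m <- encode_texts(c("alpha beta", "alpha beta"), enc)
  expect_identical(m[1L, ], m[2L, ])
  norms <- sqrt(rowSums(m^2))
  expect_equal(norms, rep(1, 2), tolerance = 1e-12)
  m2 <- encode_texts(c("chemical X", "disease Y"), enc)
  expect_false(isTRUE(all.equal(m2[1L, ], m2[2L, ])))
  expect_equal(ncol(m2), 64L)
  expect_error(encode_texts(character(), enc), "non-empty")
})

test_that("cosine similarity matches closed forms and rejects degenerate input", {
  expect_equal(cosine_similarity(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  # invariant to positive rescaling
  expect_equal(cosine_similarity(c(1, 2, 3), c(3, 1, 2)),
               cosine_similarity(10 * c(1, 2, 3), 0.2 * c(3, 1, 2)))
  expect_error(cosine_similarity(c(1, 0), c(0, 0)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "equal dimensions")
})

# independent oracle: exhaustive cosine scoring + full sort
brute_force_selection <- function(question, store, enc, mode, count) {
  q <- encode_texts(question, enc)[1L, ]
  sims <- apply(encode_texts(store$chunks$text, enc), 1L,
                function(v) sum(q * v) / sqrt(sum(q^2) * sum(v^2)))
  ord <- if (mode == "top") order(-sims, store$chunks$chunk_id, method = "radix")
         else order(sims, store$chunks$chunk_id, method = "radix")
  store$chunks$chunk_id[ord[seq_len(min(count, length(ord)))]]
}

random_store <- function(n_chunks, vocab) {
  texts <- vapply(seq_len(n_chunks), function(i) {
    paste(sample(vocab, sample(3:8, 1L), replace = TRUE), collapse = " ")
  }, character(1))
  recs <- lapply(seq_len(n_chunks), function(i) {
    knowledge_record(sprintf("r%04d", i), texts[[i]])
  })
  build_chunk_store(recs, strategies = "paragraph")
}

test_that("chunk selection equals brute-force cosine sort on random stores", {
  enc <- hash_encoder(dim = 48L)
  vocab <- c("gene", "disease", "chemical", "induces", "binds", "patient",
             "cohort", "dose", "response", "mutation", "pathway", "risk")
  withr::local_seed(99)
  for (trial in 1:100) {
    store <- random_store(sample(5:200, 1L), vocab)
    question <- paste(sample(vocab, 5L), collapse = " ")
    mode <- sample(c("top", "bottom"), 1L)
    count <- sample(1:5, 1L)
    count <- min(count, nrow(store$chunks))
    got <- select_relevant_chunks(question, store, enc, mode = mode,
                                  count = count)
    expect_identical(got$chunk_id,
                     brute_force_selection(question, store, enc, mode, count))
    expect_true(all(got$similarity >= -1 & got$similarity <= 1))
  }
})

test_that("selection handles count 0, oversize counts and text ties", {
  suite <- standard_suite()
  store <- build_chunk_store(suite$records[1:3])
  enc <- hash_encoder()
  expect_equal(nrow(select_relevant_chunks("anything", store, enc, count = 0L)), 0L)
  expect_warning(
    all_of_them <- select_relevant_chunks("anything", store, enc,
                                          count = nrow(store$chunks) + 50L),
    "exceeds store size")
  expect_equal(nrow(all_of_them), nrow(store$chunks))

  # identical token multisets tie; the smaller chunk id wins
  tie <- build_chunk_store(list(knowledge_record("a1", "same tokens here"),
                                knowledge_record("a2", "same here tokens")),
                           strategies = "sentence")
  got <- select_relevant_chunks("same tokens here", tie, enc, count = 1L)
  expect_equal(got$chunk_id, "a1:S:001")
})

test_that("top-n results are a superset-prefix of top-m for n >= m", {
  suite <- standard_suite()
  store <- build_chunk_store(suite$records[1:6])
  enc <- hash_encoder()
  q <- "does the exposure induce the condition"
  top5 <- select_relevant_chunks(q, store, enc, count = 5L)
  for (m in 1:5) {
    expect_identical(select_relevant_chunks(q, store, enc, count = m)$chunk_id,
                     top5$chunk_id[seq_len(m)])
  }
})

test_that("scaling a chunk's vector leaves the selection unchanged", {
  # encoder contract test via a custom backend with unnormalized vectors
  base <- hash_encoder(dim = 32L)
  scaled <- text_encoder("scaled", 32L, function(texts) {
    3.7 * base$encode(texts)
  })
  suite <- standard_suite()
  store <- build_chunk_store(suite$records[1:4])
  q <- "induces exposure in patients"
  expect_identical(
    select_relevant_chunks(q, store, base, count = 3L)$chunk_id,
    select_relevant_chunks(q, store, scaled, count = 3L)$chunk_id)
})
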