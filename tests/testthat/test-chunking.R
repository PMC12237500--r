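test_that("sentence splitting handles plain boundaries, abbreviations and degenerate input", {
  expect_equal(split_sentences("A. B. C."), c("A.", "B.", "C."))
  # dosing abbreviation "i.v." does not end a sentence
  expect_equal(split_sentences("Dosage was 5 mg/kg i.v. daily. Seizures stopped."),
               c("Dosage was 5 mg/kg i.v. daily.", "Seizures stopped."))
  expect_equal(split_sentences("a single clause without terminal punctuation"),
               "a single clause without terminal punctuation")
  expect_equal(split_sentences("Was it safe? Mostly. Trials continue!"),
               c("Was it safe?", "Mostly.", "Trials continue!"))
  # "No." abbreviates "number" and does not end a sentence
  expect_equal(split_sentences("Patient No. 5 improved. Follow-up ended."),
               c("Patient No. 5 improved.", "Follow-up ended."))
  expect_error(split_sentences("   "), "non-empty")
})

test_that("concatenating sentences reproduces the paragraph modulo whitespace", {
  paragraphs <- c(
    "Rats received 10 mg/kg i.p. for 5 days. Histology followed. No deaths occurred.",
    "Fig. 2 shows the dose-response. The effect plateaued at day 3.",
    "One sentence only.",
    "Mean wt. gain was 3 g. Controls gained 5 g."
  )
  for (p in paragraphs) {
    s <- split_sentences(p)
    expect_equal(paste(s, collapse = " "), trimws(gsub("[[:space:]]+", " ", p)))
  }
})

test_that("sliding windows follow the stride rule with an end-anchored final window", {
  s <- paste0("s", 1:5)
  w <- window_segments(s, k = 3L, d = 2L)
  expect_equal(unclass(w)[1:2], list(s[1:3], s[3:5]), ignore_attr = TRUE)
  expect_length(w, 2L)

  # 6 sentences: starts 1, 3; s6 uncovered -> append the last-3 window
  s6 <- paste0("s", 1:6)
  w6 <- window_segments(s6, k = 3L, d = 2L)
  expect_length(w6, 3L)
  expect_equal(w6[[3L]], s6[4:6])
  expect_equal(attr(w6, "starts"), c(1L, 3L, 4L))

  # N <= k collapses to one window
  expect_equal(window_segments(paste0("s", 1:2), k = 3L),
               list(c("s1", "s2")), ignore_attr = TRUE)

  expect_error(window_segments(s, k = 3L, d = 4L), "1 <= d <= k")
  expect_error(window_segments(character(), k = 3L), "non-empty")
})

test_that("window overlap, coverage and count laws hold for all N <= 30, k <= 5, d <= k", {
  for (n in 1:30) {
    s <- sprintf("u%02d", seq_len(n))
    for (k in 1:5) {
      for (d in 1:k) {
        w <- window_segments(s, k = k, d = d)
        starts <- attr(w, "starts")
        if (n <= k) {
          expect_length(w, 1L)
          expect_equal(w[[1L]], s)
          next
        }
        # stride-d count law with end-anchor correction
        base <- floor((n - k) / d) + 1L
        covered_by_base <- (base - 1L) * d + k
        expected <- base + as.integer(covered_by_base < n)
        expect_length(w, expected)
        # consecutive stride-d windows share exactly k - d sentences
        for (j in seq_len(base - 1L)) {
          expect_length(intersect(w[[j]], w[[j + 1L]]), k - d)
        }
        # the end-anchored window, when present, overlaps at least k - d
        if (expected > base) {
          expect_gte(length(intersect(w[[base]], w[[base + 1L]])), k - d)
          expect_equal(w[[length(w)]], s[(n - k + 1L):n])
        }
        # coverage: every sentence appears in some window
        expect_setequal(unique(unlist(w)), s)
        # final window always ends at the last sentence
        expect_equal(utils::tail(w[[length(w)]], 1L), s[[n]])
      }
    }
  }
})

test_that("chunk stores merge strategies, deduplicate and order deterministically", {
  # one single-sentence paragraph: all three strategies collapse to 1 chunk
  one <- knowledge_record("p1", "Only one sentence here.")
  store1 <- build_chunk_store(list(one))
  expect_equal(nrow(store1$chunks), 1L)

  # five sentences, defaults k=3, d=2: 5 sentence + 2 window + 1 paragraph
  para <- paste("First finding stands. Second point follows. Third result holds.",
                "Fourth item appears. Fifth note closes.")
  five <- knowledge_record("p2", para)
  store5 <- build_chunk_store(list(five))
  expect_equal(nrow(store5$chunks), 8L)
  expect_equal(as.vector(table(store5$chunks$strategy)[c("P", "S", "W")]),
               c(1L, 5L, 2L))

  # chunk ids are unique and the store is sorted by chunk id
  expect_false(anyDuplicated(store5$chunks$chunk_id) > 0L)
  expect_equal(store5$chunks$chunk_id,
               store5$chunks$chunk_id[order(store5$chunks$chunk_id, method = "radix")])

  # no two chunks share normalized text; duplicates keep the smallest id
  dup <- knowledge_record("p3", c("Same sentence text.", "Same   sentence text."))
  stored <- build_chunk_store(list(dup), strategies = "sentence")
  expect_equal(nrow(stored$chunks), 1L)
  expect_equal(stored$chunks$chunk_id, "p3:S:001")

  # determinism
  expect_identical(build_chunk_store(list(five, one)),
                   build_chunk_store(list(five, one)))
})

test_that("rebuilding a store from its own chunks is a dedup fixed point", {
  suite <- standard_suite()
  store <- build_chunk_store(suite$records[1:5])
  again <- build_chunk_store(
    list(knowledge_record("p9", store$chunks$text)), strategies = "paragraph")
  expect_equal(sort(again$chunks$text), sort(unique(store$chunks$text)))
})

test_that("chunk stores round-trip through JSON-lines serialization", {
  suite <- standard_suite()
  store <- build_chunk_store(suite$records[1:3])
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_chunk_store(store, path)
  back <- read_chunk_store(path)
  expect_equal(back$chunks, store$chunks)
  expect_equal(back$strategies, store$strategies)
  expect_equal(back$n_records, store$n_records)
})
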