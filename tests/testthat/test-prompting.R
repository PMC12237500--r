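make_instance <- function(head_surface = "lidocaine", tail_surface = "seizures",
                          schema = schema_cdr()) {
  p <- sprintf("Patients on %s developed %s.", head_surface, tail_surface)
  relation_instance("d1",
                    tiny_entity("c1", schema$head_type, head_surface, p),
                    tiny_entity("d1", schema$tail_type, tail_surface, p),
                    "positive", schema)
}

test_that("questions instantiate the schema template with first-mention surfaces", {
  q <- build_question(make_instance("X", "Y"), schema_cdr())
  expect_equal(q$text, "Does chemical X induce disease Y?")

  qg <- build_question(make_instance("G", "D", schema_gda()), schema_gda())
  expect_equal(qg$text, "Is gene G related to disease D?")

  # first mention is canonical when an entity has several surface forms
  p <- "Lidocaine was given; later lignocaine again. Seizures followed."
  multi <- entity("c1", "chemical",
                  list(entity_mention("Lidocaine", 0, 9),
                       entity_mention("lignocaine", 27, 37)))
  inst <- relation_instance("d1", multi,
                            tiny_entity("d1", "disease", "Seizures", p),
                            "positive")
  expect_match(build_question(inst, schema_cdr())$text, "Lidocaine")

  # type mismatch against the schema slots is an error
  expect_error(build_question(make_instance(schema = schema_gda()), schema_cdr()),
               "do not match schema")
})

test_that("chain-of-thought assets load as consecutively numbered steps", {
  for (ref in c("cdr", "gda", "ade")) {
    ct <- cot_template(ref)
    expect_gte(length(ct$steps), 2L)
    expect_equal(ct$dataset, ref)
  }
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1. Only one step."), bad)
  expect_error(cot_template(bad), "2 steps")
  writeLines(c("1. First.", "3. Misnumbered."), bad)
  expect_error(cot_template(bad), "consecutively")
})

test_that("the three prompt kinds render their fixed sections", {
  doc <- tiny_document()
  inst <- enumerate_candidate_pairs(doc, schema_cdr(), "all_pairs")[[1L]]
  q <- build_question(inst, schema_cdr())
  ct <- cot_template("cdr")

  std <- render_prompt(build_prompt(q, doc, kind = "standard"))
  expect_match(std, q$text, fixed = TRUE)
  expect_match(std, "Document:", fixed = TRUE)
  expect_false(grepl("External knowledge:", std, fixed = TRUE))
  expect_false(grepl("Reasoning steps:", std, fixed = TRUE))

  zs <- render_prompt(build_prompt(q, doc, kind = "zero_shot_cot"))
  expect_match(zs, "Let's think step by step.", fixed = TRUE)

  aug <- render_prompt(build_prompt(q, doc,
                                    retrieved = "Lidocaine induces seizures.",
                                    cot = ct, kind = "augmented"))
  expect_match(aug, "External knowledge:\n1. Lidocaine induces seizures.",
               fixed = TRUE)
  expect_match(aug, "Reasoning steps:\n1. ", fixed = TRUE)
  expect_match(aug, "2. Determine whether chemical entity lidocaine", fixed = TRUE)

  # every rendered prompt ends with the directive, exactly once
  for (txt in c(std, zs, aug)) {
    hits <- gregexpr(output_directive(), txt, fixed = TRUE)[[1L]]
    expect_length(hits, 1L)
    expect_true(endsWith(txt, output_directive()))
  }

  # kind/argument consistency
  expect_error(build_prompt(q, doc, retrieved = "x", kind = "standard"),
               "admits neither")
  expect_error(build_prompt(q, doc, cot = ct, kind = "zero_shot_cot"),
               "admits neither")
  expect_error(build_prompt(q, doc, kind = "augmented"), "augmented prompt needs")

  # rendering is pure: byte-identical across repeated builds
  expect_identical(aug, render_prompt(build_prompt(
    q, doc, retrieved = "Lidocaine induces seizures.", cot = ct,
    kind = "augmented")))
})

test_that("answer parsing keys on the last prefix occurrence, case-insensitively", {
  expect_equal(parse_answer("...therefore induction is supported. My answer is: Yes."),
               "yes")
  expect_equal(parse_answer("MY ANSWER IS:no"), "no")
  expect_equal(parse_answer("The relation likely holds."), "unparseable")
  # reasoning may quote the directive; the last occurrence decides
  expect_equal(parse_answer(
    'The task says "My answer is: Yes or No". Weighing it all, My answer is: No.'),
    "no")
  expect_equal(parse_answer("My answer is: maybe"), "unparseable")
  expect_equal(parse_answer(""), "unparseable")
  expect_equal(parse_answer("My answer is:   YES!"), "yes")
})

test_that("compliant completions always parse; non-compliant ones never do", {
  withr::local_seed(11)
  fillers <- c("Step 1 holds.", "The chunk supports this.", "Counterpoint noted.",
               'It quotes "My answer is:" in passing.')
  for (i in 1:50) {
    ans <- sample(c("Yes", "No"), 1L)
    reasoning <- paste(sample(fillers, sample(0:3, 1L), replace = TRUE),
                       collapse = " ")
    compliant <- sprintf("%s My answer is: %s.", reasoning, ans)
    expect_equal(parse_answer(compliant), tolower(ans))
  }
  expect_equal(parse_answer("No prefix anywhere, only prose."), "unparseable")
})

test_that("generation captures raw output, reasoning and parse status", {
  suite <- standard_suite()
  doc <- suite$documents[[1L]]
  inst <- enumerate_candidate_pairs(doc, suite$schema, "all_pairs")[[1L]]
  q <- build_question(inst, suite$schema)
  prompt <- build_prompt(q, doc, kind = "standard")

  oracle <- mock_oracle_backend(suite)
  out <- generate_answer(prompt, oracle)
  expect_equal(out$parsed, if (inst$gold == "positive") "yes" else "no")
  expect_match(out$raw, "My answer is:", fixed = TRUE)
  expect_false(grepl("My answer is:", out$reasoning, fixed = TRUE))

  empty <- generate_answer(prompt, mock_empty_backend())
  expect_equal(empty$parsed, "unparseable")
})

test_that("recorded cassettes replay byte-identically and reject unknown prompts", {
  suite <- standard_suite()
  doc <- suite$documents[[1L]]
  inst <- enumerate_candidate_pairs(doc, suite$schema, "all_pairs")[[1L]]
  prompt <- build_prompt(build_question(inst, suite$schema), doc,
                         kind = "standard")
  rec <- record_backend(mock_oracle_backend(suite))
  live <- generate_answer(prompt, rec)
  path <- withr::local_tempfile(fileext = ".json")
  save_cassette(rec, path)

  replay <- replay_backend(path)
  replayed <- generate_answer(prompt, replay)
  expect_identical(replayed$raw, live$raw)
  expect_identical(replayed$parsed, live$parsed)

  other <- build_prompt(build_question(inst, suite$schema), doc,
                        kind = "zero_shot_cot")
  expect_error(generate_answer(other, replay), "no recorded response")
})
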