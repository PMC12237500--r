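#' Define a generator (LLM) backend
#'
#' Generator contract: `complete(prompt_text, config)` returns the raw
#' completion text for one prompt. The shipped mock backends are pure
#' functions of the prompt text (and, where relevant, the seed in
#' `config`), so every pipeline run over them is deterministic.
#'
#' @param name Backend identity string.
#' @param complete Function of `(prompt, config)` returning a string.
#' @return An object of class `llm_backend`.
#' @export
llm_backend <- function(name, complete) {
  if (!is_string(name)) abort("`name` must be a string")
  if (!is.function(complete)) abort("`complete` must be a function")
  structure(list(name = name, complete = complete), class = "llm_backend")
}

# Build question-text -> (gold, fact) lookup for a fixture suite. Keys are
# matched against the prompt's first section (question + newline), which is
# unique per pair by construction.
suite_question_map <- function(suite) {
  map <- new.env(parent = emptyenv())
  fact_key <- paste(suite$facts$doc_id, suite$facts$head, suite$facts$tail,
                    sep = "|")
  for (doc in suite$documents) {
    for (inst in enumerate_candidate_pairs(doc, suite$schema, "all_pairs")) {
      q <- build_question(inst, suite$schema)
      i <- match(instance_key(inst), fact_key)
      assign(q$text,
             list(gold = inst$gold,
                  fact = if (is.na(i)) NA_character_ else suite$facts$fact[[i]]),
             envir = map)
    }
  }
  map
}

lookup_question <- function(map, prompt) {
  for (key in ls(map)) {
    if (startsWith(prompt, paste0(key, "\n"))) return(get(key, envir = map))
  }
  NULL
}

#' Mock generator backends for offline testing
#'
#' * `mock_oracle_backend()` answers every fixture question with its gold
#'   answer — the "perfect generator" used to validate the harness
#'   end-to-end (F1 must be exactly 1).
#' * `mock_constant_backend()` always emits the same answer (e.g. an
#'   always-yes generator, whose precision equals the positive prevalence).
#' * `mock_empty_backend()` returns an empty completion (exercises the
#'   unparseable path).
#' * `mock_gated_backend()` emulates a generator that needs grounding and
#'   guidance: a positive pair is answered correctly only when the
#'   planted knowledge sentence for that pair appears in the prompt (the
#'   retrieval-augmentation gate), and a negative pair only when the
#'   prompt carries reasoning steps (the chain-of-thought gate). Under
#'   this generator the full pipeline dominates both the no-retrieval and
#'   the no-reasoning ablation, the qualitative ordering the ablation
#'   grid checks.
#'
#' All four are pure functions of the prompt text.
#'
#' @param suite A [generate_fixture_suite()] result.
#' @param answer Constant answer for `mock_constant_backend()` (`"Yes"` or
#'   `"No"`).
#' @return An [llm_backend()].
#' @export
mock_oracle_backend <- function(suite) {
  map <- suite_question_map(suite)
  llm_backend("mock-oracle", function(prompt, config) {
    entry <- lookup_question(map, prompt)
    if (is.null(entry)) return("")
    sprintf("The document evidence settles the question. My answer is: %s.",
            if (entry$gold == "positive") "Yes" else "No")
  })
}

#' @rdname mock_oracle_backend
#' @export
mock_constant_backend <- function(answer = "Yes") {
  llm_backend(paste0("mock-always-", tolower(answer)),
              function(prompt, config) sprintf("My answer is: %s.", answer))
}

#' @rdname mock_oracle_backend
#' @export
mock_empty_backend <- function() {
  llm_backend("mock-empty", function(prompt, config) "")
}

#' @rdname mock_oracle_backend
#' @export
mock_gated_backend <- function(suite) {
  map <- suite_question_map(suite)
  llm_backend("mock-knowledge-gated", function(prompt, config) {
    entry <- lookup_question(map, prompt)
    if (is.null(entry)) return("")
    ans <- if (entry$gold == "positive") {
      if (!is.na(entry$fact) && grepl(entry$fact, prompt, fixed = TRUE))
        "Yes" else "No"
    } else {
      if (grepl("Reasoning steps:", prompt, fixed = TRUE)) "No" else "Yes"
    }
    sprintf("Working through the stated criteria step by step. My answer is: %s.",
            ans)
  })
}

#' Record and replay generator cassettes
#'
#' `record_backend()` wraps another backend and captures every
#' (prompt, response) exchange; `save_cassette()` writes the captured
#' exchanges to a JSON cassette; `replay_backend()` serves responses from
#' a cassette by exact prompt match, erroring on unknown prompts. Replays
#' of a cassette are byte-identical to the recorded run.
#'
#' @param backend The inner [llm_backend()] to record.
#' @return `record_backend()` returns an `llm_backend` with an attached
#'   recorder; `replay_backend()` returns an `llm_backend`.
#' @export
record_backend <- function(backend) {
  if (!inherits(backend, "llm_backend")) abort("`backend` must be an llm_backend")
  tape <- new.env(parent = emptyenv())
  tape$exchanges <- list()
  out <- llm_backend(paste0(backend$name, "+recorder"), function(prompt, config) {
    raw <- backend$complete(prompt, config)
    tape$exchanges[[length(tape$exchanges) + 1L]] <-
      list(prompt = prompt, response = raw)
    raw
  })
  out$tape <- tape
  out
}

#' @rdname record_backend
#' @param recorder A `record_backend()` result.
#' @param path Cassette file path (JSON).
#' @export
save_cassette <- function(recorder, path) {
  if (is.null(recorder$tape)) abort("`recorder` is not a recording backend")
  write_json_utf8(recorder$tape$exchanges, path)
}

#' @rdname record_backend
#' @export
replay_backend <- function(path) {
  exchanges <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  map <- new.env(parent = emptyenv())
  for (ex in exchanges) assign(fnv1a_hex(ex$prompt), ex$response, envir = map)
  llm_backend("cassette-replay", function(prompt, config) {
    key <- fnv1a_hex(prompt)
    if (!exists(key, envir = map, inherits = FALSE)) {
      abort("cassette has no recorded response for this prompt")
    }
    get(key, envir = map)
  })
}
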