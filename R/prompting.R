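# The constrained-answer protocol: generators must prefix their final
# answer with this exact phrase; the parser keys on its LAST occurrence.
.answer_prefix <- "My answer is:"

#' The constrained output directive
#'
#' Every prompt ends with this directive, which instructs the generator to
#' state its final answer as Yes or No prefixed with `"My answer is:"`.
#'
#' @return The directive text (string).
#' @export
output_directive <- function() {
  paste0('State your final answer as "Yes" or "No", prefixed with "',
         .answer_prefix, '".')
}

fill_slots <- function(template, head, tail) {
  out <- gsub("{head}", head, template, fixed = TRUE)
  gsub("{tail}", tail, out, fixed = TRUE)
}

#' Reframe a relation instance as a question
#'
#' Fills the schema's question template with the canonical surface form of
#' the head and tail entity (each entity's first mention). The instance's
#' entity types must match the schema's directed slots.
#'
#' @param instance A [relation_instance()].
#' @param schema A [relation_schema()].
#' @return An object of class `re_question` with fields `text`, `doc_id`,
#'   `head_id`, `tail_id`, `head_surface`, `tail_surface`.
#' @export
#' @examples
#' doc_ent <- function(id, type, surface)
#'   entity(id, type, list(entity_mention(surface, 0, nchar(surface))))
#' inst <- relation_instance("d1", doc_ent("c1", "chemical", "lidocaine"),
#'                           doc_ent("d1", "disease", "seizures"), "positive")
#' build_question(inst, schema_cdr())$text
build_question <- function(instance, schema) {
  if (!inherits(instance, "re_instance")) abort("`instance` must be a relation_instance")
  if (!identical(instance$head$type, schema$head_type) ||
      !identical(instance$tail$type, schema$tail_type)) {
    abort(sprintf("instance types (%s -> %s) do not match schema slots (%s -> %s)",
                  instance$head$type, instance$tail$type,
                  schema$head_type, schema$tail_type))
  }
  head_surface <- entity_surface(instance$head)
  tail_surface <- entity_surface(instance$tail)
  structure(list(text = fill_slots(schema$question_template,
                                   head_surface, tail_surface),
                 doc_id = instance$doc_id,
                 head_id = instance$head$entity_id,
                 tail_id = instance$tail$entity_id,
                 head_surface = head_surface,
                 tail_surface = tail_surface),
            class = "re_question")
}

#' Load a chain-of-thought template asset
#'
#' Chain-of-thought templates are shipped as plain-text assets, one
#' numbered step per line (`{head}`/`{tail}` slots allowed); they are
#' static, editable files under `inst/templates/`. A template must have at
#' least two steps, numbered consecutively from 1.
#'
#' @param ref Template identifier (`"cdr"`, `"gda"`, `"ade"`), or a path
#'   to a template file.
#' @return An object of class `cot_template` with fields `steps` and
#'   `dataset`.
#' @export
cot_template <- function(ref) {
  path <- if (file.exists(ref)) ref else {
    system.file("templates", sprintf("cot_%s.txt", ref), package = "ragre")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("no chain-of-thought template asset for '%s'", ref))
  }
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  nums <- suppressWarnings(as.integer(sub("^([0-9]+)\\..*$", "\\1", lines)))
  steps <- trimws(sub("^[0-9]+\\.\\s*", "", lines))
  if (length(steps) < 2L || anyNA(nums) || !identical(nums, seq_along(steps))) {
    abort(sprintf("template '%s' must have >= 2 steps numbered consecutively from 1", ref))
  }
  structure(list(steps = steps,
                 dataset = sub("^cot_(.*)\\.txt$", "\\1", basename(path))),
            class = "cot_template")
}

#' Assemble a prompt
#'
#' Builds one of the three prompt kinds with a fixed section order:
#'
#' * `standard` — question, then the full query document, then the output
#'   directive (no external knowledge, no reasoning steps);
#' * `zero_shot_cot` — the standard prompt with the cue sentence
#'   `"Let's think step by step."` inserted before the directive;
#' * `augmented` — question, document, a retrieved-chunk block labeled as
#'   external knowledge (when chunks were retrieved), and the numbered
#'   chain-of-thought steps (when a template is given), then the
#'   directive. An augmented prompt must carry at least one of the two
#'   enhancements; the ablation grid uses chunks-only and steps-only
#'   augmented prompts for its "w/o CoT" and "w/o RAG" rows.
#'
#' Rendering ([render_prompt()]) is a pure function of the inputs.
#'
#' @param question A [build_question()] result.
#' @param doc The query [document()].
#' @param retrieved Character vector of retrieved chunk texts (possibly
#'   empty).
#' @param cot A [cot_template()] or `NULL`. Step slots are filled with the
#'   question's entity surfaces.
#' @param kind `"standard"`, `"zero_shot_cot"` or `"augmented"`.
#' @return An object of class `re_prompt`.
#' @export
build_prompt <- function(question, doc, retrieved = character(),
                         cot = NULL,
                         kind = c("standard", "zero_shot_cot", "augmented")) {
  kind <- match.arg(kind)
  if (!inherits(question, "re_question")) abort("`question` must be an re_question")
  if (!inherits(doc, "re_document")) abort("`doc` must be a document")
  if (!is.null(cot) && !inherits(cot, "cot_template")) {
    abort("`cot` must be a cot_template or NULL")
  }
  if (kind %in% c("standard", "zero_shot_cot")) {
    if (length(retrieved) > 0L || !is.null(cot)) {
      abort(sprintf("kind '%s' admits neither retrieved chunks nor a CoT template", kind))
    }
  } else if (length(retrieved) == 0L && is.null(cot)) {
    abort("an augmented prompt needs retrieved chunks, a CoT template, or both")
  }
  steps <- if (is.null(cot)) character() else {
    vapply(cot$steps, fill_slots, character(1),
           head = question$head_surface, tail = question$tail_surface,
           USE.NAMES = FALSE)
  }
  structure(list(kind = kind, question = question,
                 document_text = document_text(doc),
                 retrieved = as.character(retrieved),
                 cot_steps = steps,
                 directive = output_directive()),
            class = "re_prompt")
}

#' Render a prompt to its final text
#'
#' @param prompt An [build_prompt()] result.
#' @return A single string; byte-identical across runs for equal inputs.
#' @export
render_prompt <- function(prompt) {
  if (!inherits(prompt, "re_prompt")) abort("`prompt` must be an re_prompt")
  sections <- c(
    prompt$question$text,
    paste0("Document:\n", prompt$document_text)
  )
  if (length(prompt$retrieved) > 0L) {
    sections <- c(sections, paste0(
      "External knowledge:\n",
      paste(sprintf("%d. %s", seq_along(prompt$retrieved), prompt$retrieved),
            collapse = "\n")))
  }
  if (length(prompt$cot_steps) > 0L) {
    sections <- c(sections, paste0(
      "Reasoning steps:\n",
      paste(sprintf("%d. %s", seq_along(prompt$cot_steps), prompt$cot_steps),
            collapse = "\n")))
  }
  if (prompt$kind == "zero_shot_cot") {
    sections <- c(sections, "Let's think step by step.")
  }
  paste(c(sections, prompt$directive), collapse = "\n\n")
}

#' @export
print.re_prompt <- function(x, ...) {
  cat(render_prompt(x), "\n")
  invisible(x)
}

#' Parse a constrained free-text answer
#'
#' Locates the last case-insensitive occurrence of the answer prefix
#' `"My answer is:"` in the raw generation; the first following token,
#' lower-cased and stripped of punctuation, is mapped to `"yes"` or
#' `"no"`. Any other token, or a missing prefix, yields `"unparseable"`.
#' Total function: never errors.
#'
#' @param raw Raw generation text.
#' @return `"yes"`, `"no"` or `"unparseable"`.
#' @export
#' @examples
#' parse_answer("Induction is supported. My answer is: Yes.")
#' parse_answer("MY ANSWER IS:no")
#' parse_answer("The relation likely holds.")
parse_answer <- function(raw) {
  if (!is_string(raw) || !nzchar(raw)) return("unparseable")
  m <- gregexpr(.answer_prefix, raw, ignore.case = TRUE, fixed = FALSE)[[1L]]
  if (m[1L] == -1L) return("unparseable")
  last <- m[length(m)]
  rest <- substring(raw, last + nchar(.answer_prefix))
  token <- sub("^[^A-Za-z]*([A-Za-z]*).*$", "\\1", rest)
  token <- tolower(token)
  if (token %in% c("yes", "no")) token else "unparseable"
}

#' Generate and parse an answer for a prompt
#'
#' Sends the rendered prompt to a generator backend, captures the raw
#' completion verbatim, parses the constrained answer, and splits off the
#' reasoning text preceding the final answer prefix.
#'
#' @param prompt An [build_prompt()] result.
#' @param backend An [llm_backend()].
#' @param config Sampling config list passed to the backend (e.g.
#'   `list(seed = 1, temperature = 0)`).
#' @return An object of class `generation_output` with fields `raw`,
#'   `reasoning`, `parsed`.
#' @export
generate_answer <- function(prompt, backend, config = list()) {
  if (!inherits(backend, "llm_backend")) abort("`backend` must be an llm_backend")
  raw <- backend$complete(render_prompt(prompt), config)
  if (!is_string(raw)) raw <- ""
  parsed <- parse_answer(raw)
  reasoning <- ""
  if (parsed != "unparseable") {
    m <- gregexpr(.answer_prefix, raw, ignore.case = TRUE)[[1L]]
    reasoning <- trimws(substr(raw, 1L, m[length(m)] - 1L))
  }
  structure(list(raw = raw, reasoning = reasoning, parsed = parsed),
            class = "generation_output")
}
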