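#' Define a binary relation schema
#'
#' A relation schema fixes the directed entity-pair task for one corpus:
#' which entity type fills the head slot, which fills the tail slot, the
#' label codes used for the positive and (optionally) negative class, the
#' question template used to reframe each candidate pair as a yes/no
#' question, and the chain-of-thought template asset attached to the task.
#'
#' Question templates carry exactly one `{head}` and one `{tail}` slot,
#' filled with entity surface forms by [build_question()].
#'
#' @param dataset_name Short name of the corpus/task (e.g. `"CDR"`).
#' @param head_type,tail_type Entity-type labels of the head and tail slot.
#'   Pair direction is fixed head -> tail (e.g. chemical -> disease); no
#'   reverse pairs are enumerated.
#' @param positive_label Label code of the positive class (e.g. `"1:CID:2"`).
#' @param negative_label Label code of the negative class, or `NULL` for
#'   corpora that annotate only positives.
#' @param question_template Template text with `{head}` and `{tail}` slots.
#' @param cot_template_ref Identifier of the chain-of-thought template asset
#'   (see [cot_template()]).
#' @return An object of class `relation_schema`.
#' @seealso [schema_cdr()], [schema_gda()], [schema_ade()]
#' @export
#' @examples
#' relation_schema("CDR", "chemical", "disease", "1:CID:2", "1:NR:2",
#'                 "Does chemical {head} induce disease {tail}?", "cdr")
relation_schema <- function(dataset_name, head_type, tail_type,
                            positive_label, negative_label = NULL,
                            question_template, cot_template_ref = tolower(dataset_name)) {
  if (!is_string(dataset_name)) abort("`dataset_name` must be a string")
  if (!is_string(head_type) || !is_string(tail_type)) {
    abort("`head_type` and `tail_type` must be strings")
  }
  if (!is_string(positive_label)) abort("`positive_label` must be a string")
  if (!is.null(negative_label)) {
    if (!is_string(negative_label)) abort("`negative_label` must be a string or NULL")
    if (identical(positive_label, negative_label)) {
      abort("`positive_label` and `negative_label` must differ")
    }
  }
  if (!is_string(question_template)) abort("`question_template` must be a string")
  n_head <- lengths(regmatches(question_template,
                               gregexpr("\\{head\\}", question_template)))
  n_tail <- lengths(regmatches(question_template,
                               gregexpr("\\{tail\\}", question_template)))
  if (n_head != 1L || n_tail != 1L) {
    abort("`question_template` must contain exactly one {head} and one {tail} slot")
  }
  structure(
    list(dataset_name = dataset_name,
         head_type = head_type, tail_type = tail_type,
         positive_label = positive_label, negative_label = negative_label,
         question_template = question_template,
         cot_template_ref = cot_template_ref),
    class = "relation_schema"
  )
}

#' Built-in relation schemas
#'
#' Schemas for the three standard binary biomedical relation-extraction
#' tasks: chemical-induced disease (CDR, labels `1:CID:2` / `1:NR:2`),
#' gene-disease association (GDA, labels `1:GDA:2` / `1:NR:2`), and
#' drug-adverse event (ADE, label `Drug-ADE`, positives only).
#'
#' @return A `relation_schema`.
#' @export
schema_cdr <- function() {
  relation_schema("CDR", "chemical", "disease",
                  positive_label = "1:CID:2", negative_label = "1:NR:2",
                  question_template = "Does chemical {head} induce disease {tail}?",
                  cot_template_ref = "cdr")
}

#' @rdname schema_cdr
#' @export
schema_gda <- function() {
  relation_schema("GDA", "gene", "disease",
                  positive_label = "1:GDA:2", negative_label = "1:NR:2",
                  question_template = "Is gene {head} related to disease {tail}?",
                  cot_template_ref = "gda")
}

#' @rdname schema_cdr
#' @export
schema_ade <- function() {
  relation_schema("ADE", "drug", "adverse_effect",
                  positive_label = "Drug-ADE", negative_label = "Drug-NR",
                  question_template = "Does drug {head} cause the adverse reaction {tail}?",
                  cot_template_ref = "ade")
}

schema_labels <- function(schema) {
  c(schema$positive_label, schema$negative_label)
}

#' @export
print.relation_schema <- function(x, ...) {
  cat(sprintf("<relation_schema> %s: %s -> %s (positive %s%s)\n",
              x$dataset_name, x$head_type, x$tail_type, x$positive_label,
              if (is.null(x$negative_label)) "" else paste0(", negative ", x$negative_label)))
  cat("  question: ", x$question_template, "\n", sep = "")
  invisible(x)
}
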