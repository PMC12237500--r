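#' Construct an entity mention
#'
#' A mention is one textual occurrence of an entity inside a document
#' passage. Character spans are 0-based and half-open (`start` inclusive,
#' `end` exclusive), as in the canonical corpus dialect; `passage_index` is
#' the 0-based index of the passage the span lies in.
#'
#' @param surface Surface form as it appears in the text.
#' @param start,end 0-based half-open character interval within the passage.
#' @param passage_index 0-based passage ordinal.
#' @return An object of class `re_mention`.
#' @export
entity_mention <- function(surface, start, end, passage_index = 0L) {
  if (!is_string(surface) || !nzchar(surface)) abort("`surface` must be non-empty text")
  if (!is_count(start) || !is_count(end)) abort("span ends must be non-negative integers")
  if (start >= end) abort("mention span must satisfy start < end")
  if (!is_count(passage_index)) abort("`passage_index` must be a non-negative integer")
  structure(list(surface = surface, start = as.integer(start),
                 end = as.integer(end), passage_index = as.integer(passage_index)),
            class = "re_mention")
}

#' Construct an entity
#'
#' An entity groups all mentions of one normalized concept within a
#' document, carries a normalized identifier (e.g. a MeSH ID or gene
#' symbol) and a type label, and optionally an official symbol used when no
#' controlled-vocabulary term exists for the identifier.
#'
#' @param entity_id Normalized identifier.
#' @param type Entity-type label (must match the schema slot it fills).
#' @param mentions Non-empty list of [entity_mention()] objects.
#' @param symbol Optional official symbol (e.g. a gene symbol).
#' @return An object of class `re_entity`.
#' @export
entity <- function(entity_id, type, mentions, symbol = NULL) {
  if (!is_string(entity_id) || !nzchar(entity_id)) abort("`entity_id` must be non-empty text")
  if (!is_string(type)) abort("`type` must be a string")
  if (!is.list(mentions) || length(mentions) == 0L) {
    abort(sprintf("entity '%s' must have at least one mention", entity_id))
  }
  ok <- vapply(mentions, inherits, logical(1), what = "re_mention")
  if (!all(ok)) abort("`mentions` must all be entity_mention objects")
  if (!is.null(symbol) && !is_string(symbol)) abort("`symbol` must be a string or NULL")
  structure(list(entity_id = entity_id, type = type,
                 mentions = mentions, symbol = symbol),
            class = "re_entity")
}

# Canonical surface form of an entity: its first mention's surface.
entity_surface <- function(ent) ent$mentions[[1L]]$surface

#' Construct a document
#'
#' A document is a titled sequence of text passages with typed, normalized
#' entity annotations and gold binary relation labels. Every gold label
#' must reference declared entity ids; when a schema is supplied, label
#' codes are checked against it and mention spans are checked against
#' passage lengths.
#'
#' @param doc_id Document identifier.
#' @param title Document title.
#' @param passages Character vector of passage texts (ordered).
#' @param entities List of [entity()] objects.
#' @param gold_labels Data frame with columns `head`, `tail`, `label`
#'   (entity ids and a schema label code per row); may have zero rows.
#' @param schema Optional [relation_schema()] used to validate label codes.
#' @return An object of class `re_document`.
#' @export
document <- function(doc_id, title, passages, entities,
                     gold_labels = empty_gold(), schema = NULL) {
  if (!is_string(doc_id) || !nzchar(doc_id)) abort("`doc_id` must be non-empty text")
  if (!is_string(title)) abort("`title` must be a string")
  if (!is.character(passages) || length(passages) == 0L) {
    abort(sprintf("document '%s': `passages` must be a non-empty character vector", doc_id))
  }
  if (!is.list(entities)) abort("`entities` must be a list of entity objects")
  ok <- vapply(entities, inherits, logical(1), what = "re_entity")
  if (length(entities) > 0L && !all(ok)) abort("`entities` must all be entity objects")
  if (!is.data.frame(gold_labels) ||
      !all(c("head", "tail", "label") %in% names(gold_labels))) {
    abort("`gold_labels` must be a data frame with columns head, tail, label")
  }
  gold_labels <- data.frame(head = as.character(gold_labels$head),
                            tail = as.character(gold_labels$tail),
                            label = as.character(gold_labels$label),
                            stringsAsFactors = FALSE)
  ids <- vapply(entities, function(e) e$entity_id, character(1))
  if (anyDuplicated(ids)) abort(sprintf("document '%s': duplicate entity ids", doc_id))
  missing <- setdiff(unique(c(gold_labels$head, gold_labels$tail)), ids)
  if (length(missing) > 0L) {
    abort(sprintf("document '%s': gold labels reference undeclared entities: %s",
                  doc_id, paste(missing, collapse = ", ")))
  }
  for (e in entities) {
    for (m in e$mentions) {
      if (m$passage_index >= length(passages)) {
        abort(sprintf("document '%s', entity '%s': passage_index %d out of range",
                      doc_id, e$entity_id, m$passage_index))
      }
      if (m$end > nchar(passages[[m$passage_index + 1L]])) {
        abort(sprintf("document '%s', entity '%s': span [%d,%d) exceeds passage length",
                      doc_id, e$entity_id, m$start, m$end))
      }
    }
  }
  if (!is.null(schema)) {
    bad <- setdiff(unique(gold_labels$label), schema_labels(schema))
    if (length(bad) > 0L) {
      abort(sprintf("document '%s': unknown label code '%s'", doc_id, bad[[1L]]))
    }
  }
  structure(list(doc_id = doc_id, title = title, passages = passages,
                 entities = entities, gold_labels = gold_labels),
            class = "re_document")
}

empty_gold <- function() {
  data.frame(head = character(), tail = character(), label = character(),
             stringsAsFactors = FALSE)
}

doc_entity <- function(doc, entity_id) {
  for (e in doc$entities) if (identical(e$entity_id, entity_id)) return(e)
  abort(sprintf("document '%s': no entity '%s'", doc$doc_id, entity_id))
}

# Full text of a document: title then passages.
document_text <- function(doc) {
  paste(c(doc$title, doc$passages), collapse = "\n")
}

#' Construct a relation instance
#'
#' One candidate entity pair of a document together with its gold binary
#' answer. Head and tail types must match the schema's directed slots.
#'
#' @param doc_id Owning document id.
#' @param head,tail [entity()] objects filling the head and tail slot.
#' @param gold `"positive"` or `"negative"`.
#' @param schema Optional [relation_schema()]; when given, slot types are
#'   checked.
#' @return An object of class `re_instance`.
#' @export
relation_instance <- function(doc_id, head, tail, gold, schema = NULL) {
  if (!inherits(head, "re_entity") || !inherits(tail, "re_entity")) {
    abort("`head` and `tail` must be entity objects")
  }
  gold <- match.arg(gold, c("positive", "negative"))
  if (!is.null(schema)) {
    if (!identical(head$type, schema$head_type)) {
      abort(sprintf("head entity '%s' has type '%s'; schema requires '%s'",
                    head$entity_id, head$type, schema$head_type))
    }
    if (!identical(tail$type, schema$tail_type)) {
      abort(sprintf("tail entity '%s' has type '%s'; schema requires '%s'",
                    tail$entity_id, tail$type, schema$tail_type))
    }
  }
  structure(list(doc_id = doc_id, head = head, tail = tail, gold = gold),
            class = "re_instance")
}

instance_key <- function(inst) {
  paste(inst$doc_id, inst$head$entity_id, inst$tail$entity_id, sep = "|")
}

#' @export
print.re_document <- function(x, ...) {
  cat(sprintf("<document> %s: %d passage(s), %d entities, %d gold label(s)\n",
              x$doc_id, length(x$passages), length(x$entities), nrow(x$gold_labels)))
  invisible(x)
}

#' @export
print.re_instance <- function(x, ...) {
  cat(sprintf("<instance> %s: %s -> %s [%s]\n", x$doc_id,
              x$head$entity_id, x$tail$entity_id, x$gold))
  invisible(x)
}
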