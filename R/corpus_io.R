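#' Read a relation-extraction corpus
#'
#' Reads document-level relation-extraction corpora into the package's
#' document model. Three dialects are supported:
#'
#' * `canonical` — the package's own JSON dialect (see [write_corpus()]):
#'   an array of records with `doc_id`, `title`, `passages`, `entities`
#'   (each with `entity_id`, `type`, optional `symbol`, and `mentions`
#'   holding 0-based half-open `start`/`end` spans plus `passage_index`),
#'   and `gold_labels` rows of `head`/`tail`/`label`.
#' * `docred_json` — DocRED-style JSON as distributed for CDR/GDA:
#'   tokenized sentences in `sents`, entity clusters in `vertexSet`
#'   (mentions with `name`, `sent_id`, token `pos`, `type`, optional `id`),
#'   and `labels` triples `h`/`t`/`r`. Each sentence becomes one passage;
#'   token offsets are converted to character spans.
#' * `pair_list` — a TSV with header columns `doc_id`, `text`, `head`,
#'   `tail`, `label` (one annotated pair per row, ADE-style); rows sharing
#'   a `doc_id` are folded into one single-passage document and entity
#'   spans are located by first occurrence of the surface form.
#'
#' Label codes are validated against the schema; a malformed record raises
#' an error naming the record index and offending field.
#'
#' @param path Path to the corpus file.
#' @param dialect One of `"canonical"`, `"docred_json"`, `"pair_list"`.
#' @param schema A [relation_schema()].
#' @return A list of [document()] objects.
#' @export
read_corpus <- function(path, dialect = c("canonical", "docred_json", "pair_list"),
                        schema) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  if (!inherits(schema, "relation_schema")) abort("`schema` must be a relation_schema")
  switch(dialect,
         canonical = read_corpus_canonical(path, schema),
         docred_json = read_corpus_docred(path, schema),
         pair_list = read_corpus_pairlist(path, schema))
}

read_corpus_canonical <- function(path, schema) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    for (fld in c("doc_id", "title", "passages", "entities")) {
      if (is.null(r[[fld]])) {
        abort(sprintf("canonical record %d: missing field '%s'", i, fld))
      }
    }
    ents <- lapply(r$entities, function(e) {
      if (is.null(e$entity_id) || is.null(e$type) || is.null(e$mentions)) {
        abort(sprintf("canonical record %d: entity missing entity_id/type/mentions", i))
      }
      mens <- lapply(e$mentions, function(m) {
        entity_mention(m$surface, m$start, m$end, m$passage_index %||% 0L)
      })
      entity(e$entity_id, e$type, mens, symbol = e$symbol)
    })
    gl <- r$gold_labels %||% list()
    gold <- if (length(gl) == 0L) empty_gold() else {
      data.frame(head = vapply(gl, function(g) g$head %||% abort(
                   sprintf("canonical record %d: gold label missing 'head'", i)), character(1)),
                 tail = vapply(gl, function(g) g$tail %||% abort(
                   sprintf("canonical record %d: gold label missing 'tail'", i)), character(1)),
                 label = vapply(gl, function(g) g$label %||% abort(
                   sprintf("canonical record %d: gold label missing 'label'", i)), character(1)),
                 stringsAsFactors = FALSE)
    }
    document(r$doc_id, r$title, unlist(r$passages, use.names = FALSE),
             ents, gold, schema = schema)
  })
}

read_corpus_docred <- function(path, schema) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$sents) || is.null(r$vertexSet)) {
      abort(sprintf("docred record %d: missing field 'sents' or 'vertexSet'", i))
    }
    sent_tokens <- lapply(r$sents, function(s) unlist(s, use.names = FALSE))
    passages <- vapply(sent_tokens, paste, character(1), collapse = " ")
    ents <- lapply(seq_along(r$vertexSet), function(j) {
      cluster <- r$vertexSet[[j]]
      if (length(cluster) == 0L) {
        abort(sprintf("docred record %d: empty vertexSet cluster %d", i, j))
      }
      mens <- lapply(cluster, function(m) {
        if (is.null(m$sent_id) || is.null(m$pos) || is.null(m$name)) {
          abort(sprintf("docred record %d: mention in cluster %d missing name/sent_id/pos", i, j))
        }
        toks <- sent_tokens[[m$sent_id + 1L]]
        s <- m$pos[[1L]]; e <- m$pos[[2L]]
        start <- if (s == 0L) 0L else sum(nchar(toks[seq_len(s)])) + s
        text <- paste(toks[(s + 1L):e], collapse = " ")
        entity_mention(m$name, start, start + nchar(text), m$sent_id)
      })
      eid <- cluster[[1L]]$id %||% cluster[[1L]]$name
      entity(eid, cluster[[1L]]$type %||% "unknown", mens,
             symbol = cluster[[1L]]$symbol)
    })
    labels <- r$labels %||% list()
    gold <- if (length(labels) == 0L) empty_gold() else {
      data.frame(
        head = vapply(labels, function(l) ents[[l$h + 1L]]$entity_id, character(1)),
        tail = vapply(labels, function(l) ents[[l$t + 1L]]$entity_id, character(1)),
        label = vapply(labels, function(l) as.character(l$r), character(1)),
        stringsAsFactors = FALSE)
    }
    document(r$doc_id %||% r$title %||% sprintf("docred-%d", i),
             r$title %||% "", passages, ents, gold, schema = schema)
  })
}

read_corpus_pairlist <- function(path, schema) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("doc_id", "text", "head", "tail", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    abort(sprintf("pair_list file: missing column(s) %s", paste(miss, collapse = ", ")))
  }
  lapply(split(seq_len(nrow(tab)), factor(tab$doc_id, levels = unique(tab$doc_id))),
         function(rows) {
    sub <- tab[rows, , drop = FALSE]
    text <- sub$text[[1L]]
    mk_entity <- function(surface, type, row_index) {
      pos <- regexpr(surface, text, fixed = TRUE)
      if (pos < 0L) {
        abort(sprintf("pair_list record %d: field '%s' surface '%s' not found in text",
                      row_index, if (type == schema$head_type) "head" else "tail", surface))
      }
      entity(surface, type,
             list(entity_mention(surface, pos - 1L, pos - 1L + nchar(surface), 0L)))
    }
    heads <- unique(sub$head)
    tails <- unique(sub$tail)
    ents <- c(lapply(heads, function(s) mk_entity(s, schema$head_type,
                                                  rows[match(s, sub$head)])),
              lapply(tails, function(s) mk_entity(s, schema$tail_type,
                                                  rows[match(s, sub$tail)])))
    gold <- data.frame(head = sub$head, tail = sub$tail, label = sub$label,
                       stringsAsFactors = FALSE)
    document(sub$doc_id[[1L]], "", text, ents, gold, schema = schema)
  }) |> unname()
}

#' Write a corpus in the canonical JSON dialect
#'
#' Serializes documents to the canonical dialect read back by
#' [read_corpus()] with `dialect = "canonical"`. The writer is
#' deterministic: the same documents always produce byte-identical output.
#'
#' @param documents List of [document()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(documents, path) {
  recs <- lapply(documents, function(d) {
    list(doc_id = d$doc_id, title = d$title, passages = as.list(d$passages),
         entities = lapply(d$entities, function(e) {
           out <- list(entity_id = e$entity_id, type = e$type,
                       mentions = lapply(e$mentions, function(m) {
                         list(surface = m$surface, start = m$start, end = m$end,
                              passage_index = m$passage_index)
                       }))
           if (!is.null(e$symbol)) out$symbol <- e$symbol
           out
         }),
         gold_labels = if (nrow(d$gold_labels) == 0L) list() else
           lapply(seq_len(nrow(d$gold_labels)), function(i) {
             list(head = d$gold_labels$head[[i]], tail = d$gold_labels$tail[[i]],
                  label = d$gold_labels$label[[i]])
           }))
  })
  write_json_utf8(recs, path)
}

#' Enumerate candidate relation instances of a document
#'
#' In `all_pairs` mode every (head-type, tail-type) entity combination of
#' the document becomes an instance, labeled positive iff a gold positive
#' label exists for the pair and negative otherwise — the evaluation
#' convention for corpora such as CDR and GDA. In `annotated_only` mode
#' only pairs listed in the document's gold labels are returned (ADE-style
#' corpora that annotate positives only); `negative_ratio` optionally adds
#' that many sampled unannotated pairs per annotated pair as negatives.
#'
#' @param doc A [document()].
#' @param schema A [relation_schema()].
#' @param mode `"all_pairs"` or `"annotated_only"`.
#' @param negative_ratio Non-negative number; in `annotated_only` mode,
#'   target ratio of sampled negative pairs to annotated pairs (0 = none).
#' @param seed Optional integer seed for negative sampling.
#' @return A list of [relation_instance()] objects (possibly empty).
#' @export
enumerate_candidate_pairs <- function(doc, schema,
                                      mode = c("all_pairs", "annotated_only"),
                                      negative_ratio = 0, seed = NULL) {
  mode <- match.arg(mode)
  heads <- Filter(function(e) identical(e$type, schema$head_type), doc$entities)
  tails <- Filter(function(e) identical(e$type, schema$tail_type), doc$entities)
  gold <- doc$gold_labels
  pos_key <- paste(gold$head[gold$label == schema$positive_label],
                   gold$tail[gold$label == schema$positive_label], sep = "|")
  if (mode == "all_pairs") {
    if (length(heads) == 0L || length(tails) == 0L) return(list())
    out <- list()
    for (h in heads) {
      for (t in tails) {
        g <- if (paste(h$entity_id, t$entity_id, sep = "|") %in% pos_key)
          "positive" else "negative"
        out[[length(out) + 1L]] <- relation_instance(doc$doc_id, h, t, g, schema)
      }
    }
    return(out)
  }
  # annotated_only
  out <- lapply(seq_len(nrow(gold)), function(i) {
    relation_instance(doc$doc_id,
                      doc_entity(doc, gold$head[[i]]),
                      doc_entity(doc, gold$tail[[i]]),
                      if (gold$label[[i]] == schema$positive_label) "positive"
                      else "negative",
                      schema)
  })
  if (negative_ratio > 0) {
    ann_key <- paste(gold$head, gold$tail, sep = "|")
    pool <- list()
    for (h in heads) for (t in tails) {
      if (!(paste(h$entity_id, t$entity_id, sep = "|") %in% ann_key)) {
        pool[[length(pool) + 1L]] <- relation_instance(doc$doc_id, h, t,
                                                       "negative", schema)
      }
    }
    n_take <- min(length(pool), ceiling(negative_ratio * length(out)))
    if (n_take > 0L) {
      idx <- if (is.null(seed)) seq_len(n_take) else
        with_seed(seed, sample(length(pool), n_take))
      out <- c(out, pool[idx])
    }
  }
  out
}
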