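# Abbreviations that never end a sentence even when followed by a capital.
# Lower-cased, with trailing period. Kept deliberately small and biomedical.
.abbreviations <- c(
  "e.g.", "i.e.", "i.v.", "i.m.", "i.p.", "p.o.", "s.c.", "b.i.d.", "t.i.d.",
  "vs.", "cf.", "al.", "et.", "fig.", "figs.", "ref.", "refs.", "no.", "nos.",
  "dr.", "prof.", "st.", "ca.", "approx.", "resp.", "spp.", "sp.", "wt.",
  "mol.", "min.", "max.", "inj."
)

#' Split a paragraph into sentences
#'
#' Deterministic rule-based sentence splitter: a sentence boundary is a run
#' of `.`, `!` or `?` followed by whitespace and an upper-case letter or
#' digit, unless the token ending at the punctuation is a known
#' abbreviation (e.g. `"i.v."`, `"e.g."`, `"Fig."`). The concatenation of
#' the returned sentences, modulo inter-sentence whitespace, reproduces the
#' input paragraph.
#'
#' @param paragraph Non-empty paragraph text.
#' @return Character vector of sentences (each trimmed, in order).
#' @export
#' @examples
#' split_sentences("Dosage was 5 mg/kg i.v. daily. Seizures stopped.")
split_sentences <- function(paragraph) {
  if (!is_string(paragraph) || !nzchar(trimws(paragraph))) {
    abort("`paragraph` must be non-empty text")
  }
  text <- squish(paragraph)
  m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(text)
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  keep <- vapply(ends, function(e) {
    # token ending at the punctuation run
    prefix <- substr(text, 1L, e)
    token <- sub("^.*[[:space:]]", "", prefix)
    !(tolower(token) %in% .abbreviations)
  }, logical(1))
  ends <- ends[keep]
  if (length(ends) == 0L) return(text)
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(text))
  sentences <- trimws(substring(text, starts, stops))
  sentences[nzchar(sentences)]
}

#' Group sentences into sliding windows
#'
#' Groups `k` consecutive sentences with stride `d`: windows start at
#' sentence 1, 1+d, 1+2d, ... while a full window of `k` sentences fits.
#' Consecutive windows therefore share `k - d` sentences (one sentence at
#' the defaults `k = 3`, `d = 2`). If the final sentence would otherwise be
#' uncovered, one end-anchored window of the last `k` sentences is
#' appended, so the last window always ends at the last sentence. If there
#' are at most `k` sentences, the single window of all of them is
#' returned.
#'
#' @param sentences Non-empty character vector of sentences.
#' @param k Window size in sentences (default 3).
#' @param d Stride in sentences, `1 <= d <= k` (default 2).
#' @return List of character vectors (the windows), with attribute
#'   `starts` giving each window's 1-based start sentence index.
#' @export
#' @examples
#' window_segments(paste0("s", 1:6), k = 3, d = 2)
window_segments <- function(sentences, k = 3L, d = 2L) {
  if (!is.character(sentences) || length(sentences) == 0L) {
    abort("`sentences` must be a non-empty character vector")
  }
  if (!is_count(k, 1L)) abort("`k` must be an integer >= 1")
  if (!is_count(d, 1L) || d > k) abort("`d` must satisfy 1 <= d <= k")
  n <- length(sentences)
  if (n <= k) {
    out <- list(sentences)
    attr(out, "starts") <- 1L
    return(out)
  }
  starts <- seq.int(1L, n - k + 1L, by = d)
  if (starts[length(starts)] + k - 1L < n) {
    starts <- c(starts, n - k + 1L)
  }
  out <- lapply(starts, function(s) sentences[s:(s + k - 1L)])
  attr(out, "starts") <- as.integer(starts)
  out
}

#' Build a deduplicated chunk store from abstract records
#'
#' Applies the selected segmentation strategies to every paragraph of
#' every record and merges the results into one deterministically ordered
#' store:
#'
#' * `paragraph` — each abstract paragraph is one chunk (tag `P`);
#' * `sentence` — each sentence is one chunk (tag `S`);
#' * `window` — sliding windows of `k` sentences with stride `d` (tag `W`),
#'   see [window_segments()].
#'
#' Chunk ids are `"<pmid>:<tag>:<index>"` with a per-record running index
#' per strategy. Chunks whose normalized text collides keep only the
#' lexicographically smallest chunk id, and the store is sorted by chunk
#' id, so repeated builds from the same records are identical.
#'
#' @param records List of [knowledge_record()] objects.
#' @param strategies Subset of `c("sentence", "window", "paragraph")`.
#' @param k,d Window parameters passed to [window_segments()].
#' @return An object of class `chunk_store`: a list with `chunks` (data
#'   frame: `chunk_id`, `text`, `pmid`, `strategy`, `paragraph_index`,
#'   `sentence_start`, `sentence_end`), `strategies`, `n_records`.
#' @export
build_chunk_store <- function(records,
                              strategies = c("sentence", "window", "paragraph"),
                              k = 3L, d = 2L) {
  if (length(records) == 0L) abort("`records` must be non-empty")
  strategies <- match.arg(strategies, c("sentence", "window", "paragraph"),
                          several.ok = TRUE)
  rows <- list()
  add <- function(pmid, tag, index, text, para, s_start, s_end) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chunk_id = sprintf("%s:%s:%03d", pmid, tag, index),
      text = squish(text), pmid = pmid, strategy = tag,
      paragraph_index = para, sentence_start = s_start, sentence_end = s_end,
      stringsAsFactors = FALSE)
  }
  for (rec in records) {
    if (!inherits(rec, "knowledge_record")) abort("`records` must be knowledge_record objects")
    idx <- c(P = 0L, S = 0L, W = 0L)
    for (pi in seq_along(rec$paragraphs)) {
      para <- rec$paragraphs[[pi]]
      sentences <- split_sentences(para)
      if ("paragraph" %in% strategies) {
        idx[["P"]] <- idx[["P"]] + 1L
        add(rec$pmid, "P", idx[["P"]], para, pi, 1L, length(sentences))
      }
      if ("sentence" %in% strategies) {
        for (si in seq_along(sentences)) {
          idx[["S"]] <- idx[["S"]] + 1L
          add(rec$pmid, "S", idx[["S"]], sentences[[si]], pi, si, si)
        }
      }
      if ("window" %in% strategies) {
        wins <- window_segments(sentences, k = k, d = d)
        starts <- attr(wins, "starts")
        for (wi in seq_along(wins)) {
          idx[["W"]] <- idx[["W"]] + 1L
          add(rec$pmid, "W", idx[["W"]], paste(wins[[wi]], collapse = " "),
              pi, starts[[wi]], starts[[wi]] + length(wins[[wi]]) - 1L)
        }
      }
    }
  }
  chunks <- do.call(rbind, rows)
  chunks <- chunks[radix_order(chunks$chunk_id), , drop = FALSE]
  chunks <- chunks[!duplicated(chunks$text), , drop = FALSE]
  rownames(chunks) <- NULL
  structure(list(chunks = chunks, strategies = radix_sort(strategies),
                 n_records = length(records)),
            class = "chunk_store")
}

#' @export
print.chunk_store <- function(x, ...) {
  cat(sprintf("<chunk_store> %d chunks from %d record(s), strategies: %s\n",
              nrow(x$chunks), x$n_records, paste(x$strategies, collapse = ", ")))
  invisible(x)
}

#' Serialize / load a chunk store
#'
#' Chunk stores are serialized as JSON lines of
#' `(chunk_id, text, provenance)`; the writer is deterministic.
#'
#' @param store A `chunk_store`.
#' @param path File path.
#' @return `read_chunk_store()` returns a `chunk_store`.
#' @export
write_chunk_store <- function(store, path) {
  ch <- store$chunks
  lines <- vapply(seq_len(nrow(ch)), function(i) {
    as.character(jsonlite::toJSON(list(
      chunk_id = ch$chunk_id[[i]], text = ch$text[[i]],
      provenance = list(pmid = ch$pmid[[i]],
                        paragraph_index = ch$paragraph_index[[i]],
                        sentence_start = ch$sentence_start[[i]],
                        sentence_end = ch$sentence_end[[i]])),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines,
               sprintf("#meta %s", jsonlite::toJSON(
                 list(strategies = store$strategies, n_records = store$n_records),
                 auto_unbox = TRUE))),
             con = con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_chunk_store
#' @export
read_chunk_store <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_line <- grep("^#meta ", lines, value = TRUE)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", meta_line[[1L]]))
  lines <- lines[!startsWith(lines, "#meta ") & nzchar(lines)]
  rows <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    data.frame(chunk_id = r$chunk_id, text = r$text, pmid = r$provenance$pmid,
               strategy = strsplit(r$chunk_id, ":", fixed = TRUE)[[1L]][[2L]],
               paragraph_index = r$provenance$paragraph_index,
               sentence_start = r$provenance$sentence_start,
               sentence_end = r$provenance$sentence_end,
               stringsAsFactors = FALSE)
  })
  chunks <- do.call(rbind, rows)
  structure(list(chunks = chunks, strategies = meta$strategies,
                 n_records = meta$n_records),
            class = "chunk_store")
}
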