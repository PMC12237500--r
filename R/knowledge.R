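#' Construct a knowledge record
#'
#' A literature abstract serving as external knowledge: an article
#' identifier (PMID) plus the ordered paragraphs of its abstract.
#' Paragraphs are whitespace-normalized and must be non-empty.
#'
#' @param pmid Article identifier (text).
#' @param paragraphs Character vector of abstract paragraphs.
#' @return An object of class `knowledge_record`.
#' @export
knowledge_record <- function(pmid, paragraphs) {
  if (!is_string(pmid) || !nzchar(pmid)) abort("`pmid` must be non-empty text")
  paragraphs <- squish(as.character(paragraphs))
  paragraphs <- paragraphs[nzchar(paragraphs)]
  if (length(paragraphs) == 0L) {
    abort(sprintf("record '%s': paragraphs empty after normalization", pmid))
  }
  structure(list(pmid = pmid, paragraphs = paragraphs), class = "knowledge_record")
}

#' Load an entity-to-term mapping table
#'
#' Reads a two-column TSV (`entity_id`, `term`) mapping normalized entity
#' identifiers to controlled vocabulary terms (MeSH terms, or official
#' symbols where no MeSH term exists).
#'
#' @param path TSV path with header columns `entity_id` and `term`.
#' @return A named character vector (names = entity ids).
#' @export
read_term_mapping <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!all(c("entity_id", "term") %in% names(tab))) {
    abort("term mapping must have columns 'entity_id' and 'term'")
  }
  if (any(!nzchar(tab$term))) abort("term mapping contains empty terms")
  stats::setNames(as.character(tab$term), as.character(tab$entity_id))
}

#' Resolve an entity to its controlled search term
#'
#' Returns the mapped controlled term (typically a MeSH term) for the
#' entity; entities absent from the mapping fall back to their official
#' symbol (the convention for e.g. genes without MeSH entries). An entity
#' that is unmapped and has no symbol is an error.
#'
#' @param ent An [entity()].
#' @param mapping Named character vector from [read_term_mapping()] (may be
#'   empty).
#' @return The controlled term (string).
#' @export
resolve_entity_term <- function(ent, mapping = character()) {
  if (!inherits(ent, "re_entity")) abort("`ent` must be an entity")
  term <- unname(mapping[ent$entity_id])
  if (length(term) == 1L && !is.na(term)) return(term)
  if (!is.null(ent$symbol)) return(ent$symbol)
  abort(sprintf("entity '%s' has no term mapping and no official symbol",
                ent$entity_id))
}

#' Construct a ranked hit list
#'
#' A hit list pairs article identifiers with relevance ranks (1 = best),
#' emulating a literature service's relevance ("best match") ordering with
#' an explicit rank column. Ranks must be unique and contiguous from 1.
#'
#' @param pmid Character vector of article identifiers.
#' @param rank Integer ranks; defaults to input order.
#' @return A data frame with columns `pmid`, `rank`, sorted by rank.
#' @export
ranked_hits <- function(pmid = character(), rank = seq_along(pmid)) {
  pmid <- as.character(pmid)
  rank <- as.integer(rank)
  if (length(pmid) != length(rank)) abort("`pmid` and `rank` lengths differ")
  if (length(pmid) > 0L) {
    if (anyDuplicated(pmid)) abort("hit list contains duplicate pmids")
    if (!identical(radix_sort(rank), seq_along(rank))) {
      abort("ranks must be unique and contiguous from 1")
    }
  }
  out <- data.frame(pmid = pmid, rank = rank, stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

as_ranked_hits <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("pmid", "rank") %in% names(x))) {
      abort(sprintf("%s must have columns 'pmid' and 'rank'", what))
    }
    return(ranked_hits(x$pmid, x$rank))
  }
  ranked_hits(as.character(x))
}

#' Select article identifiers for an entity pair
#'
#' Implements the co-occurrence selection rule used to build the external
#' knowledge base: if any articles mention both terms together, keep them
#' all when there are at most `cap`, otherwise the `cap` best-ranked. If no
#' article contains both terms, fall back to the `fallback_k` best-ranked
#' hits of each single-term query and merge them (first entity's list
#' first, duplicates collapsed to their first occurrence).
#'
#' @param cooccurrence_hits,entity1_hits,entity2_hits Ranked hit lists
#'   ([ranked_hits()] data frames, or plain character vectors taken as
#'   already rank-ordered).
#' @param cap Maximum number of co-occurrence articles kept (default 10).
#' @param fallback_k Per-entity article count in the fallback branch
#'   (default 5).
#' @return Character vector of selected pmids, in selection order
#'   (duplicate-free, length <= `cap` and <= `2 * fallback_k` in the
#'   fallback branch).
#' @export
select_pmids <- function(cooccurrence_hits, entity1_hits = ranked_hits(),
                         entity2_hits = ranked_hits(),
                         cap = 10L, fallback_k = 5L) {
  if (!is_count(cap, 1L) || !is_count(fallback_k, 1L) || cap < fallback_k) {
    abort("`cap` and `fallback_k` must satisfy cap >= fallback_k >= 1")
  }
  co <- as_ranked_hits(cooccurrence_hits, "cooccurrence_hits")
  if (nrow(co) > 0L) {
    return(utils::head(co$pmid, cap))
  }
  h1 <- as_ranked_hits(entity1_hits, "entity1_hits")
  h2 <- as_ranked_hits(entity2_hits, "entity2_hits")
  merged <- c(utils::head(h1$pmid, fallback_k), utils::head(h2$pmid, fallback_k))
  merged[!duplicated(merged)]
}

#' Offline knowledge backend
#'
#' Builds a deterministic literature-service backend from a local store of
#' abstract records plus a query index mapping term queries to ranked
#' pmids. The backend satisfies the knowledge-backend contract used by the
#' pipeline: `query_cooccurrence(term1, term2)` and `query_single(term)`
#' return [ranked_hits()] frames, `fetch(pmid)` returns a
#' [knowledge_record()] or `NULL` for unknown pmids. Queries are symmetric
#' in the two terms and pure functions of the store.
#'
#' @param records List of [knowledge_record()] objects.
#' @param query_index Data frame with columns `key`, `pmid`, `rank`, where
#'   `key` is `"pair:<termA>||<termB>"` (terms in C-locale sorted order) or
#'   `"term:<term>"`.
#' @return An object of class `knowledge_backend`.
#' @seealso [read_knowledge_store()], [select_pmids()], [fetch_records()]
#' @export
offline_knowledge_backend <- function(records, query_index) {
  if (!all(c("key", "pmid", "rank") %in% names(query_index))) {
    abort("`query_index` must have columns key, pmid, rank")
  }
  store <- new.env(parent = emptyenv())
  for (r in records) {
    if (!inherits(r, "knowledge_record")) abort("`records` must be knowledge_record objects")
    assign(r$pmid, r, envir = store)
  }
  lookup <- function(key) {
    sub <- query_index[query_index$key == key, , drop = FALSE]
    ranked_hits(sub$pmid[order(sub$rank)], seq_len(nrow(sub)))
  }
  structure(
    list(
      name = "offline-store",
      query_cooccurrence = function(term1, term2) lookup(pair_key(term1, term2)),
      query_single = function(term) lookup(paste0("term:", term)),
      fetch = function(pmid) {
        if (exists(pmid, envir = store, inherits = FALSE)) {
          get(pmid, envir = store)
        } else {
          NULL
        }
      },
      n_records = length(records)
    ),
    class = "knowledge_backend"
  )
}

pair_key <- function(term1, term2) {
  both <- c(term1, term2)
  paste0("pair:", paste(both[radix_order(both)], collapse = "||"))
}

#' Fetch abstract records for a list of pmids
#'
#' Fetches one [knowledge_record()] per resolvable pmid from a backend,
#' preserving input order. Unresolvable pmids are skipped with a warning
#' and counted in the `skipped` attribute of the result.
#'
#' @param pmids Character vector of article identifiers.
#' @param backend A `knowledge_backend`.
#' @return List of [knowledge_record()] with attribute `skipped` (count of
#'   unresolvable pmids).
#' @export
fetch_records <- function(pmids, backend) {
  if (!inherits(backend, "knowledge_backend")) abort("`backend` must be a knowledge_backend")
  out <- list()
  skipped <- 0L
  for (p in pmids) {
    rec <- backend$fetch(p)
    if (is.null(rec)) {
      warning(sprintf("pmid '%s' could not be fetched; skipping", p), call. = FALSE)
      skipped <- skipped + 1L
    } else {
      out[[length(out) + 1L]] <- rec
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read and write an offline knowledge store
#'
#' The offline store is serialized as JSON lines (one record per line,
#' fields `pmid` and `paragraphs`) plus a query-index TSV with columns
#' `key`, `pmid`, `rank` (see [offline_knowledge_backend()] for the key
#' syntax). Writers are deterministic.
#'
#' @param records_path JSON-lines file of records.
#' @param index_path Query-index TSV.
#' @return `read_knowledge_store()` returns a `knowledge_backend`.
#' @export
read_knowledge_store <- function(records_path, index_path) {
  lines <- readLines(records_path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    knowledge_record(r$pmid, unlist(r$paragraphs, use.names = FALSE))
  })
  idx <- utils::read.delim(index_path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  offline_knowledge_backend(records, idx)
}

#' @rdname read_knowledge_store
#' @param records List of [knowledge_record()] objects to write.
#' @param query_index Query-index data frame to write.
#' @export
write_knowledge_store <- function(records, query_index, records_path, index_path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(list(pmid = r$pmid,
                                       paragraphs = as.list(r$paragraphs)),
                                  auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(records_path, open = "wb")
  writeLines(lines, con = con, useBytes = TRUE)
  close(con)
  write_tsv(query_index, index_path)
  invisible(records_path)
}

# Deterministic TSV writer (no quoting, fixed eol).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "", eol = "\n")
  invisible(path)
}
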