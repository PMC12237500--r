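#' Deterministic hashed bag-of-words encoder
#'
#' A fully offline sentence encoder satisfying the encoder contract used
#' by the retrieval stage: texts are lower-cased, tokenized on
#' non-alphanumeric characters, each token is hashed (FNV-1a) into one of
#' `dim` buckets, and the resulting count vector is L2-normalized. The
#' same text always maps to the same unit vector, and texts with distinct
#' token multisets almost surely map to distinct vectors, which is what
#' top-k cosine retrieval needs. Production deployments plug in a neural
#' sentence encoder behind the same contract ([text_encoder()]).
#'
#' @param dim Embedding dimension (number of hash buckets), default 256.
#' @param name Backend identity string.
#' @return A `text_encoder` object.
#' @export
hash_encoder <- function(dim = 256L, name = "hashed-bow") {
  if (!is_count(dim, 2L)) abort("`dim` must be an integer >= 2")
  dim <- as.integer(dim)
  bucket_cache <- new.env(parent = emptyenv())
  bucket_of <- function(token) {
    if (exists(token, envir = bucket_cache, inherits = FALSE)) {
      return(get(token, envir = bucket_cache))
    }
    b <- as.integer(fnv1a(token) %% dim) + 1L
    assign(token, b, envir = bucket_cache)
    b
  }
  encode_one <- function(text) {
    tokens <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
    tokens <- tokens[nzchar(tokens)]
    v <- numeric(dim)
    if (length(tokens) == 0L) {
      v[1L] <- 1
      return(v)
    }
    for (tok in tokens) {
      b <- bucket_of(tok)
      v[b] <- v[b] + 1
    }
    v / sqrt(sum(v^2))
  }
  text_encoder(name = name, dim = dim,
               encode = function(texts) {
                 t(vapply(texts, encode_one, numeric(dim), USE.NAMES = FALSE))
               })
}

#' Define a sentence-encoder backend
#'
#' Encoder contract: `encode(texts)` must return one numeric vector of the
#' declared dimension per input text, deterministically within one backend
#' version. Embeddings are memoized per backend keyed by the normalized
#' text, so repeated encodes of the same chunk are free.
#'
#' @param name Backend identity string.
#' @param dim Declared embedding dimension.
#' @param encode Function taking a character vector and returning a
#'   numeric matrix with one row per text and `dim` columns.
#' @return A `text_encoder` object.
#' @export
text_encoder <- function(name, dim, encode) {
  if (!is_string(name)) abort("`name` must be a string")
  if (!is_count(dim, 1L)) abort("`dim` must be a positive integer")
  if (!is.function(encode)) abort("`encode` must be a function")
  cache <- new.env(parent = emptyenv())
  structure(list(name = name, dim = as.integer(dim), encode = encode,
                 cache = cache),
            class = "text_encoder")
}

#' Encode texts with an encoder backend
#'
#' @param texts Non-empty character vector.
#' @param encoder A [text_encoder()].
#' @return Numeric matrix, one row per text, `encoder$dim` columns.
#' @export
encode_texts <- function(texts, encoder) {
  if (!is.character(texts) || length(texts) == 0L) {
    abort("`texts` must be a non-empty character vector")
  }
  if (!inherits(encoder, "text_encoder")) abort("`encoder` must be a text_encoder")
  keys <- squish(texts)
  out <- matrix(NA_real_, nrow = length(texts), ncol = encoder$dim)
  todo <- !vapply(keys, exists, logical(1), envir = encoder$cache,
                  inherits = FALSE, USE.NAMES = FALSE)
  if (any(todo)) {
    fresh <- encoder$encode(texts[todo])
    if (!is.matrix(fresh) || nrow(fresh) != sum(todo) || ncol(fresh) != encoder$dim) {
      abort(sprintf("encoder backend '%s' returned a malformed embedding matrix",
                    encoder$name))
    }
    ti <- which(todo)
    for (j in seq_along(ti)) {
      assign(keys[[ti[j]]], fresh[j, ], envir = encoder$cache)
    }
  }
  for (i in seq_along(keys)) out[i, ] <- get(keys[[i]], envir = encoder$cache)
  out
}

#' Cosine similarity between two vectors
#'
#' `u . v / (||u|| ||v||)`, in `[-1, 1]`; invariant to positive rescaling
#' of either argument. Zero vectors and dimension mismatches are errors.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("`u` and `v` must have equal dimensions")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity is undefined for zero vectors")
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

#' Select the most (or least) similar chunks for a question
#'
#' Encodes the question and every chunk in the store, scores cosine
#' similarity, and returns the `count` most similar chunks in descending
#' similarity (`mode = "top"`) or the `count` least similar in ascending
#' similarity (`mode = "bottom"`, the low-similarity ablation). Ties are
#' broken by ascending chunk id; `count = 0` returns an empty result (the
#' no-knowledge ablation); `count` beyond the store size returns all
#' chunks with a warning.
#'
#' @param question_text The query text.
#' @param store A [build_chunk_store()] result.
#' @param encoder A [text_encoder()].
#' @param mode `"top"` or `"bottom"`.
#' @param count Number of chunks to select (default 1).
#' @return Data frame with columns `chunk_id`, `text`, `similarity`.
#' @export
select_relevant_chunks <- function(question_text, store, encoder,
                                   mode = c("top", "bottom"), count = 1L) {
  mode <- match.arg(mode)
  if (!inherits(store, "chunk_store") || nrow(store$chunks) == 0L) {
    abort("`store` must be a non-empty chunk_store")
  }
  if (!is_count(count)) abort("`count` must be a non-negative integer")
  empty <- data.frame(chunk_id = character(), text = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  if (count == 0L) return(empty)
  n <- nrow(store$chunks)
  if (count > n) {
    warning(sprintf("count %d exceeds store size %d; returning all chunks",
                    count, n), call. = FALSE)
    count <- n
  }
  q <- encode_texts(question_text, encoder)[1L, ]
  emb <- encode_texts(store$chunks$text, encoder)
  sims <- vapply(seq_len(n), function(i) cosine_similarity(q, emb[i, ]),
                 numeric(1))
  ord <- if (mode == "top") {
    order(-sims, store$chunks$chunk_id, method = "radix")
  } else {
    order(sims, store$chunks$chunk_id, method = "radix")
  }
  sel <- ord[seq_len(count)]
  data.frame(chunk_id = store$chunks$chunk_id[sel],
             text = store$chunks$text[sel],
             similarity = sims[sel],
             stringsAsFactors = FALSE)
}
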