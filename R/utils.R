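# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
abort <- function(...) stop(..., call. = FALSE)

# Collapse internal whitespace and strip ends; case-preserving.
squish <- function(x) trimws(gsub("[[:space:]]+", " ", x))

# Locale-independent (C collation) ordering, so serialized artifacts are
# byte-identical across systems.
radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) x[radix_order(x)]

# FNV-1a 32-bit hash over UTF-8 bytes, used for token bucketing in the
# fallback encoder and for prompt fingerprints in audit logs. The xor only
# touches the low 8 bits; the multiply is split into 16-bit halves to stay
# within double precision.
fnv1a <- function(text) {
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- (h - lo8) + bitwXor(as.integer(lo8), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  h
}

fnv1a_hex <- function(text) {
  h <- fnv1a(text)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= min
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Deterministic UTF-8 JSON writer used by every serializer in the package.
write_json_utf8 <- function(x, path, pretty = FALSE) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = pretty)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con = con, useBytes = TRUE)
  invisible(path)
}
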