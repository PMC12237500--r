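# Shared helpers: tiny in-code fixtures for the document model and a
# memoized standard fixture suite for the end-to-end tests.

tiny_entity <- function(id, type, surface, passage, passage_index = 0L) {
  pos <- regexpr(surface, passage, fixed = TRUE)
  stopifnot(pos > 0L)
  entity(id, type,
         list(entity_mention(surface, pos - 1L, pos - 1L + nchar(surface),
                             passage_index)))
}

# One CDR-style document: 1 chemical, 1 disease, configurable gold label.
tiny_document <- function(label = "1:CID:2", doc_id = "d1") {
  p1 <- "Patients on lidocaine developed seizures after infusion."
  document(doc_id, "A case report.", p1,
           list(tiny_entity("c1", "chemical", "lidocaine", p1),
                tiny_entity("d1", "disease", "seizures", p1)),
           data.frame(head = "c1", tail = "d1", label = label,
                      stringsAsFactors = FALSE),
           schema = schema_cdr())
}

# A document with nh chemicals and nt diseases and no gold positives
# except those listed in `positives` (list of c(head, tail) id pairs).
multi_pair_document <- function(nh = 2L, nt = 3L, positives = list(),
                                doc_id = "m1") {
  chems <- sprintf("chem%done", seq_len(nh))
  dis <- sprintf("dis%dosis", seq_len(nt))
  p1 <- paste(c(sprintf("Drug %s was administered.", chems),
                sprintf("Condition %s was observed.", dis)), collapse = " ")
  ents <- c(lapply(seq_len(nh), function(i)
              tiny_entity(sprintf("c%d", i), "chemical", chems[[i]], p1)),
            lapply(seq_len(nt), function(i)
              tiny_entity(sprintf("d%d", i), "disease", dis[[i]], p1)))
  gold <- if (length(positives) == 0L) {
    data.frame(head = character(), tail = character(), label = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(positives, function(p)
      data.frame(head = p[[1L]], tail = p[[2L]], label = "1:CID:2",
                 stringsAsFactors = FALSE)))
  }
  document(doc_id, "Multi-pair report.", p1, ents, gold, schema = schema_cdr())
}

# Standard-conditions fixture suite, generated once per test run.
standard_suite <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7L) {
    key <- as.character(seed)
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, generate_fixture_suite(fixture_config(), seed = seed),
             envir = cache)
    }
    get(key, envir = cache)
  }
})

suite_pipeline_backends <- function(suite, llm) {
  pipeline_backends(llm, suite_backend(suite), hash_encoder(),
                    suite_mapping(suite))
}

# Independent brute-force contingency recomputation used as the metrics
# oracle: operates on plain logical vectors, not on package objects.
brute_force_metrics <- function(pred_yes, gold_yes) {
  tp <- sum(pred_yes & gold_yes)
  fp <- sum(pred_yes & !gold_yes)
  fn <- sum(!pred_yes & gold_yes)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(tp = tp, fp = fp, fn = fn, tn = sum(!pred_yes & !gold_yes),
       precision = p, recall = r, f1 = f)
}
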