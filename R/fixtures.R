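# Synthetic fixture suite: a miniature relation-extraction corpus plus a
# matching offline knowledge store, built so the whole pipeline (reading,
# pair enumeration, term resolution, PMID selection, chunking, retrieval,
# prompting, scoring) is exercisable without any downloads.

.syllables_head <- c("dar", "vex", "lino", "pram", "zol", "bex", "cor", "fen",
                     "mig", "tol")
.syllables_tail <- c("card", "neuro", "derm", "hepat", "nephro", "myo", "oste",
                     "gastr", "pulmo", "angi")
.syllables_noise <- c("plac", "grel", "stib", "quor", "velt", "juna", "brix",
                      "oswe", "klyn", "drup")

# Deterministic pseudo-name for vocabulary index i (1-based): two syllables
# plus a class suffix; injective for i <= 100.
synth_name <- function(i, syllables, suffix) {
  a <- syllables[((i - 1L) %% 10L) + 1L]
  b <- syllables[(((i - 1L) %/% 10L) %% 10L) + 1L]
  paste0(b, a, suffix)
}

#' Configuration for the synthetic fixture suite
#'
#' Defaults define the standard offline study conditions used throughout
#' the package's tests: 20 documents with 1-2 head (chemical-like) and 1-3
#' tail (disease-like) entities each (roughly 60 candidate pairs), a
#' positive-pair prevalence of 0.5, and 10 distractor abstracts of
#' unrelated vocabulary in the knowledge store.
#'
#' @param n_docs Number of documents (>= 1).
#' @param prevalence Probability that a candidate pair is positive, in
#'   (0, 1).
#' @param heads_per_doc,tails_per_doc Integer vectors of admissible
#'   per-document entity counts (sampled uniformly).
#' @param n_distractors Number of unrelated distractor abstracts.
#' @param vocab_heads,vocab_tails Vocabulary sizes (<= 100 each).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_docs = 20L, prevalence = 0.5,
                           heads_per_doc = 1:2, tails_per_doc = 1:3,
                           n_distractors = 10L,
                           vocab_heads = 40L, vocab_tails = 40L) {
  if (!is_count(n_docs, 1L)) abort("`n_docs` must be an integer >= 1")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie in (0, 1)")
  }
  if (!is_count(n_distractors)) abort("`n_distractors` must be a non-negative integer")
  structure(list(n_docs = as.integer(n_docs), prevalence = prevalence,
                 heads_per_doc = as.integer(heads_per_doc),
                 tails_per_doc = as.integer(tails_per_doc),
                 n_distractors = as.integer(n_distractors),
                 vocab_heads = as.integer(vocab_heads),
                 vocab_tails = as.integer(vocab_tails)),
            class = "fixture_config")
}

#' Generate a synthetic fixture suite
#'
#' Builds a deterministic miniature study: documents with typed entity
#' mentions and binary gold labels under the chemical-disease schema, a
#' knowledge store in which every positive pair has a planted abstract
#' whose first sentence states the relation with both entity terms, and
#' every entity term has a background abstract mentioning it alone
#' (reached through the single-term fallback for negative pairs), plus
#' unrelated distractor abstracts. The suite also carries the oracle
#' (gold answer per candidate pair), the planted fact per positive pair,
#' and the entity-to-term mapping.
#'
#' Regeneration with the same seed and config is byte-identical after
#' serialization with [write_fixture_suite()].
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @return An object of class `fixture_suite`: `documents`, `records`,
#'   `query_index`, `oracle`, `facts`, `mapping`, `schema`, `seed`,
#'   `config`.
#' @export
generate_fixture_suite <- function(config = fixture_config(), seed = 1L) {
  if (!inherits(config, "fixture_config")) abort("`config` must be a fixture_config")
  if (!is_count(seed)) abort("`seed` must be a non-negative integer")
  schema <- schema_cdr()
  head_vocab <- vapply(seq_len(config$vocab_heads), synth_name, character(1),
                       syllables = .syllables_head, suffix = "ine")
  tail_vocab <- vapply(seq_len(config$vocab_tails), synth_name, character(1),
                       syllables = .syllables_tail, suffix = "osis")
  with_seed(seed, {
    documents <- list()
    oracle <- list()
    facts <- list()
    used_heads <- integer()
    used_tails <- integer()
    pair_facts <- new.env(parent = emptyenv())  # term-pair -> fact text
    pair_gold <- new.env(parent = emptyenv())   # term-pair -> logical
    # the truth of a relation is a property of the term pair, not of the
    # document it is asked in: decide once, reuse everywhere
    pair_positive <- function(t1, t2) {
      key <- pair_key(t1, t2)
      if (!exists(key, envir = pair_gold, inherits = FALSE)) {
        assign(key, stats::runif(1L) < config$prevalence, envir = pair_gold)
      }
      get(key, envir = pair_gold)
    }
    for (di in seq_len(config$n_docs)) {
      doc_id <- sprintf("FIX%04d", di)
      sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)
      hi <- sample(seq_len(config$vocab_heads), sample_one(config$heads_per_doc))
      ti <- sample(seq_len(config$vocab_tails), sample_one(config$tails_per_doc))
      used_heads <- union(used_heads, hi)
      used_tails <- union(used_tails, ti)
      h_terms <- head_vocab[hi]
      t_terms <- tail_vocab[ti]
      title <- sprintf("Clinical observations on %s exposure.", h_terms[[1L]])
      p1 <- paste(c(sprintf("Patients received %s during the study period.", h_terms),
                    sprintf("Several cases of %s were documented.", t_terms)),
                  collapse = " ")
      p2 <- paste("Associations between the administered agents and the",
                  "observed conditions were assessed. Clinical records were",
                  "reviewed for each patient.")
      mk_ent <- function(idx, term, type, prefix) {
        pos <- regexpr(term, p1, fixed = TRUE)
        entity(sprintf("%s%03d", prefix, idx), type,
               list(entity_mention(term, pos - 1L, pos - 1L + nchar(term), 0L)))
      }
      ents <- c(mapply(mk_ent, hi, h_terms,
                       MoreArgs = list(type = schema$head_type, prefix = "C"),
                       SIMPLIFY = FALSE),
                mapply(mk_ent, ti, t_terms,
                       MoreArgs = list(type = schema$tail_type, prefix = "D"),
                       SIMPLIFY = FALSE))
      gold <- list()
      for (a in seq_along(hi)) {
        for (b in seq_along(ti)) {
          positive <- pair_positive(h_terms[[a]], t_terms[[b]])
          head_id <- sprintf("C%03d", hi[[a]])
          tail_id <- sprintf("D%03d", ti[[b]])
          gold[[length(gold) + 1L]] <- data.frame(
            head = head_id, tail = tail_id,
            label = if (positive) schema$positive_label else schema$negative_label,
            stringsAsFactors = FALSE)
          oracle[[length(oracle) + 1L]] <- data.frame(
            doc_id = doc_id, head = head_id, tail = tail_id,
            answer = if (positive) "yes" else "no", stringsAsFactors = FALSE)
          if (positive) {
            fact <- sprintf("%s induces %s in exposed patients.",
                            h_terms[[a]], t_terms[[b]])
            assign(pair_key(h_terms[[a]], t_terms[[b]]), fact, envir = pair_facts)
            facts[[length(facts) + 1L]] <- data.frame(
              doc_id = doc_id, head = head_id, tail = tail_id, fact = fact,
              stringsAsFactors = FALSE)
          }
        }
      }
      documents[[di]] <- document(doc_id, title, c(p1, p2), ents,
                                  do.call(rbind, gold), schema = schema)
    }
    # Knowledge store: planted co-occurrence abstracts, per-term background
    # abstracts, and unrelated distractors.
    records <- list()
    index <- list()
    pmid_n <- 0L
    next_pmid <- function() {
      pmid_n <<- pmid_n + 1L
      sprintf("9%06d", pmid_n)
    }
    add_index <- function(key, pmid) {
      prev <- sum(vapply(index, function(r) r$key == key, logical(1)))
      index[[length(index) + 1L]] <<- data.frame(key = key, pmid = pmid,
                                                 rank = prev + 1L,
                                                 stringsAsFactors = FALSE)
    }
    pair_keys <- radix_sort(ls(pair_facts))
    for (key in pair_keys) {
      fact <- get(key, envir = pair_facts)
      pmid <- next_pmid()
      records[[length(records) + 1L]] <- knowledge_record(pmid, c(
        paste(fact, "This association was consistent across multiple cohorts."),
        "Mechanistic studies support a causal role for the exposure."))
      add_index(key, pmid)
    }
    all_terms <- c(head_vocab[radix_sort(used_heads)],
                   tail_vocab[radix_sort(used_tails)])
    for (term in all_terms) {
      pmid <- next_pmid()
      records[[length(records) + 1L]] <- knowledge_record(pmid, c(
        sprintf("The pharmacology and epidemiology of %s have been reviewed extensively.", term),
        "No conclusions about specific causal associations were drawn."))
      add_index(paste0("term:", term), pmid)
    }
    # Planted abstracts also answer single-term queries for their two terms.
    for (key in pair_keys) {
      terms <- strsplit(sub("^pair:", "", key), "||", fixed = TRUE)[[1L]]
      pmid <- index[[match(TRUE, vapply(index, function(r) r$key == key,
                                        logical(1)))]]$pmid
      for (term in terms) add_index(paste0("term:", term), pmid)
    }
    for (j in seq_len(config$n_distractors)) {
      term <- synth_name(j, .syllables_noise, "ium")
      pmid <- next_pmid()
      records[[length(records) + 1L]] <- knowledge_record(pmid, c(
        sprintf("Baseline characteristics of %s cohorts were tabulated.", term),
        "Follow-up surveys showed stable enrollment over time."))
      add_index(paste0("term:", term), pmid)
    }
    ids <- c(sprintf("C%03d", radix_sort(used_heads)),
             sprintf("D%03d", radix_sort(used_tails)))
    terms <- c(head_vocab[radix_sort(used_heads)],
               tail_vocab[radix_sort(used_tails)])
    structure(list(documents = documents,
                   records = records,
                   query_index = do.call(rbind, index),
                   oracle = do.call(rbind, oracle),
                   facts = if (length(facts) > 0L) do.call(rbind, facts) else
                     data.frame(doc_id = character(), head = character(),
                                tail = character(), fact = character(),
                                stringsAsFactors = FALSE),
                   mapping = data.frame(entity_id = ids, term = terms,
                                        stringsAsFactors = FALSE),
                   schema = schema, seed = as.integer(seed), config = config),
              class = "fixture_suite")
  })
}

#' @export
print.fixture_suite <- function(x, ...) {
  cat(sprintf("<fixture_suite> %d documents, %d knowledge records, %d candidate pairs (%d positive), seed %d\n",
              length(x$documents), length(x$records), nrow(x$oracle),
              sum(x$oracle$answer == "yes"), x$seed))
  invisible(x)
}

#' Fixture suite accessors
#'
#' Convenience views of a fixture suite: `suite_mapping()` returns the
#' entity-to-term mapping as a named vector, `suite_backend()` wraps the
#' suite's knowledge store as an [offline_knowledge_backend()], and
#' `suite_instances()` enumerates all candidate pairs of all documents.
#'
#' @param suite A [generate_fixture_suite()] result.
#' @return See each function's description.
#' @export
suite_mapping <- function(suite) {
  stats::setNames(suite$mapping$term, suite$mapping$entity_id)
}

#' @rdname suite_mapping
#' @export
suite_backend <- function(suite) {
  offline_knowledge_backend(suite$records, suite$query_index)
}

#' @rdname suite_mapping
#' @export
suite_instances <- function(suite) {
  unlist(lapply(suite$documents, enumerate_candidate_pairs,
                schema = suite$schema, mode = "all_pairs"),
         recursive = FALSE)
}

#' Serialize / load a fixture suite
#'
#' A suite is serialized as a directory: `corpus.json` (canonical corpus
#' dialect), `knowledge.jsonl` + `query_index.tsv` (offline knowledge
#' store), `oracle.tsv`, `facts.tsv`, `mapping.tsv`, and `manifest.json`
#' (seed and config). Serialization is deterministic: equal suites yield
#' byte-identical directories.
#'
#' @param suite A [generate_fixture_suite()] result.
#' @param dir Directory path (created if missing).
#' @return `read_fixture_suite()` returns a `fixture_suite`.
#' @export
write_fixture_suite <- function(suite, dir) {
  if (!inherits(suite, "fixture_suite")) abort("`suite` must be a fixture_suite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(suite$documents, file.path(dir, "corpus.json"))
  write_knowledge_store(suite$records, suite$query_index,
                        file.path(dir, "knowledge.jsonl"),
                        file.path(dir, "query_index.tsv"))
  write_tsv(suite$oracle, file.path(dir, "oracle.tsv"))
  write_tsv(suite$facts, file.path(dir, "facts.tsv"))
  write_tsv(suite$mapping, file.path(dir, "mapping.tsv"))
  write_json_utf8(list(seed = suite$seed, schema = suite$schema$dataset_name,
                       config = unclass(suite$config)),
                  file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_fixture_suite
#' @export
read_fixture_suite <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  schema <- switch(manifest$schema, CDR = schema_cdr(), GDA = schema_gda(),
                   ADE = schema_ade(),
                   abort(sprintf("unknown schema '%s' in manifest", manifest$schema)))
  backend <- read_knowledge_store(file.path(dir, "knowledge.jsonl"),
                                  file.path(dir, "query_index.tsv"))
  lines <- readLines(file.path(dir, "knowledge.jsonl"), encoding = "UTF-8")
  records <- lapply(lines[nzchar(lines)], function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    knowledge_record(r$pmid, unlist(r$paragraphs, use.names = FALSE))
  })
  cfg <- do.call(fixture_config, manifest$config[names(manifest$config) %in%
                                                   names(formals(fixture_config))])
  structure(list(documents = read_corpus(file.path(dir, "corpus.json"),
                                         "canonical", schema),
                 records = records,
                 query_index = utils::read.delim(file.path(dir, "query_index.tsv"),
                                                 stringsAsFactors = FALSE, quote = ""),
                 oracle = utils::read.delim(file.path(dir, "oracle.tsv"),
                                            stringsAsFactors = FALSE, quote = ""),
                 facts = utils::read.delim(file.path(dir, "facts.tsv"),
                                           stringsAsFactors = FALSE, quote = ""),
                 mapping = utils::read.delim(file.path(dir, "mapping.tsv"),
                                             stringsAsFactors = FALSE, quote = ""),
                 schema = schema, seed = as.integer(manifest$seed), config = cfg),
            class = "fixture_suite")
}
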