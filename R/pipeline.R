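#' Configure one pipeline / ablation run
#'
#' An ablation config fixes every pipeline factor for one labeled run:
#' whether retrieval augmentation and chain-of-thought guidance are
#' enabled, which chunking strategies build the per-instance knowledge
#' store (the canonical variants are I = sentence, II = window, III =
#' paragraph, IV = the hybrid of all three), the retrieval mode and chunk
#' count, the window parameters, the PMID selection constants, and the
#' repeated-run protocol.
#'
#' Disabling retrieval forces the chunk count to 0; an explicit
#' `prompt_kind` of `"standard"` or `"zero_shot_cot"` likewise forces both
#' enhancements off. Otherwise the prompt kind follows from the flags:
#' augmented when either enhancement is on, standard when both are off.
#'
#' @param label Row label for result tables.
#' @param rag_enabled,cot_enabled Enable retrieval augmentation /
#'   chain-of-thought steps.
#' @param prompt_kind Optional explicit prompt kind overriding the flags
#'   (`"standard"`, `"zero_shot_cot"`).
#' @param strategies Chunking strategy set (subset of
#'   `c("sentence", "window", "paragraph")`).
#' @param chunk_mode `"top"` (most similar) or `"bottom"` (the
#'   low-similarity ablation).
#' @param chunk_count Retrieved chunks per prompt (default 1).
#' @param k,d Sliding-window size and stride (defaults 3 and 2).
#' @param pmid_cap Co-occurrence article cap (default 10).
#' @param fallback_k Per-entity fallback article count (default 5).
#' @param pair_mode Candidate-pair enumeration mode (see
#'   [enumerate_candidate_pairs()]).
#' @param n_runs Number of repeated generation runs (default 3).
#' @param seeds Optional integer vector of per-run seeds (length
#'   `n_runs`); defaults to `100 + 1:n_runs`.
#' @return An object of class `ablation_config`.
#' @export
ablation_config <- function(label = "full",
                            rag_enabled = TRUE, cot_enabled = TRUE,
                            prompt_kind = NULL,
                            strategies = c("sentence", "window", "paragraph"),
                            chunk_mode = c("top", "bottom"),
                            chunk_count = 1L, k = 3L, d = 2L,
                            pmid_cap = 10L, fallback_k = 5L,
                            pair_mode = c("all_pairs", "annotated_only"),
                            n_runs = 3L, seeds = NULL) {
  chunk_mode <- match.arg(chunk_mode)
  pair_mode <- match.arg(pair_mode)
  if (!is.null(prompt_kind)) {
    prompt_kind <- match.arg(prompt_kind, c("standard", "zero_shot_cot"))
    rag_enabled <- FALSE
    cot_enabled <- FALSE
  }
  if (!rag_enabled) chunk_count <- 0L
  if (!is_count(chunk_count)) abort("`chunk_count` must be a non-negative integer")
  if (rag_enabled && chunk_count == 0L) {
    abort("retrieval augmentation with `chunk_count = 0` retrieves nothing; disable `rag_enabled` instead")
  }
  if (!is_count(n_runs, 1L)) abort("`n_runs` must be an integer >= 1")
  seeds <- if (is.null(seeds)) 100L + seq_len(n_runs) else as.integer(seeds)
  if (length(seeds) != n_runs) abort("`seeds` must have length `n_runs`")
  kind <- if (!is.null(prompt_kind)) prompt_kind
    else if (rag_enabled || cot_enabled) "augmented" else "standard"
  structure(list(label = label, rag_enabled = rag_enabled,
                 cot_enabled = cot_enabled, prompt_kind = kind,
                 strategies = strategies, chunk_mode = chunk_mode,
                 chunk_count = as.integer(chunk_count),
                 k = as.integer(k), d = as.integer(d),
                 pmid_cap = as.integer(pmid_cap),
                 fallback_k = as.integer(fallback_k),
                 pair_mode = pair_mode,
                 n_runs = as.integer(n_runs), seeds = seeds),
            class = "ablation_config")
}

#' Assemble the backend set for a pipeline run
#'
#' @param llm An [llm_backend()].
#' @param knowledge A `knowledge_backend` (required when retrieval is
#'   enabled).
#' @param encoder A [text_encoder()] (required when retrieval is enabled);
#'   defaults to the offline [hash_encoder()].
#' @param mapping Named character vector mapping entity ids to controlled
#'   terms (see [read_term_mapping()]).
#' @return A list of class `pipeline_backends`.
#' @export
pipeline_backends <- function(llm, knowledge = NULL, encoder = hash_encoder(),
                              mapping = character()) {
  if (!inherits(llm, "llm_backend")) abort("`llm` must be an llm_backend")
  structure(list(llm = llm, knowledge = knowledge, encoder = encoder,
                 mapping = mapping),
            class = "pipeline_backends")
}

#' Run the full relation-extraction pipeline
#'
#' For every candidate pair of every document: build the question; when
#' retrieval is enabled, resolve both entities to controlled terms, select
#' article identifiers by the co-occurrence rule ([select_pmids()]), fetch
#' the abstracts, build the per-instance chunk store with the configured
#' strategies, and retrieve the configured number of chunks by cosine
#' similarity; assemble the prompt for the configured kind; generate
#' `n_runs` completions (one per seed); parse each constrained answer
#' (unparseable completions default to the negative label and are
#' tallied); score each run; and aggregate mean +/- sd over runs. Every
#' intermediate artifact is kept in a per-instance audit record.
#'
#' @param documents List of [document()] objects.
#' @param schema A [relation_schema()].
#' @param config An [ablation_config()].
#' @param backends A [pipeline_backends()].
#' @return An object of class `pipeline_result`: `label`, `aggregate`
#'   ([aggregate_runs()] result), `reports` (per-run
#'   [metrics_report()]s), `audit` (per-instance records), `n_instances`.
#' @export
run_pipeline <- function(documents, schema, config, backends) {
  if (!inherits(config, "ablation_config")) abort("`config` must be an ablation_config")
  if (!inherits(backends, "pipeline_backends")) {
    abort("`backends` must be a pipeline_backends list")
  }
  if (config$rag_enabled && is.null(backends$knowledge)) {
    abort("retrieval augmentation requires a knowledge backend")
  }
  instances <- unlist(lapply(documents, enumerate_candidate_pairs,
                             schema = schema, mode = config$pair_mode),
                      recursive = FALSE)
  if (length(instances) == 0L) abort("no candidate instances to run on")
  doc_by_id <- stats::setNames(documents,
                               vapply(documents, function(d) d$doc_id, character(1)))
  cot <- if (config$cot_enabled) cot_template(schema$cot_template_ref) else NULL
  audit <- vector("list", length(instances))
  runs <- replicate(config$n_runs, vector("list", length(instances)),
                    simplify = FALSE)
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    doc <- doc_by_id[[inst$doc_id]]
    question <- build_question(inst, schema)
    pmids <- character()
    retrieved <- data.frame(chunk_id = character(), text = character(),
                            similarity = numeric(), stringsAsFactors = FALSE)
    if (config$rag_enabled) {
      term1 <- resolve_entity_term(inst$head, backends$mapping)
      term2 <- resolve_entity_term(inst$tail, backends$mapping)
      kb <- backends$knowledge
      pmids <- select_pmids(kb$query_cooccurrence(term1, term2),
                            kb$query_single(term1), kb$query_single(term2),
                            cap = config$pmid_cap,
                            fallback_k = config$fallback_k)
      records <- fetch_records(pmids, kb)
      if (length(records) > 0L) {
        store <- build_chunk_store(records, strategies = config$strategies,
                                   k = config$k, d = config$d)
        n_avail <- nrow(store$chunks)
        retrieved <- select_relevant_chunks(question$text, store,
                                            backends$encoder,
                                            mode = config$chunk_mode,
                                            count = min(config$chunk_count,
                                                        n_avail))
      }
    }
    prompt <- build_prompt(question, doc, retrieved = retrieved$text,
                           cot = cot, kind = config$prompt_kind)
    prompt_text <- render_prompt(prompt)
    run_records <- vector("list", config$n_runs)
    for (r in seq_len(config$n_runs)) {
      gen <- generate_answer(prompt, backends$llm,
                             config = list(seed = config$seeds[[r]],
                                           temperature = 0))
      predicted <- if (gen$parsed == "unparseable") "no" else gen$parsed
      runs[[r]][[i]] <- prediction(inst, predicted,
                                   parse_status = if (gen$parsed == "unparseable")
                                     "unparseable" else "parsed",
                                   raw = gen$raw)
      run_records[[r]] <- list(seed = config$seeds[[r]], raw = gen$raw,
                               parsed = gen$parsed, predicted = predicted)
    }
    audit[[i]] <- list(doc_id = inst$doc_id,
                       head = inst$head$entity_id, tail = inst$tail$entity_id,
                       gold = inst$gold, question = question$text,
                       pmids = as.list(pmids),
                       chunk_ids = as.list(retrieved$chunk_id),
                       similarities = as.list(retrieved$similarity),
                       n_retrieved = nrow(retrieved),
                       prompt_hash = fnv1a_hex(prompt_text),
                       runs = run_records)
  }
  reports <- lapply(seq_len(config$n_runs), function(r) {
    score_predictions(runs[[r]], instances, run_id = r)
  })
  structure(list(label = config$label, aggregate = aggregate_runs(reports),
                 reports = reports, audit = audit,
                 n_instances = length(instances)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> '%s' over %d instance(s):\n",
              x$label, x$n_instances))
  print(x$aggregate)
  invisible(x)
}

#' Run a grid of ablation configurations
#'
#' Runs [run_pipeline()] once per config with shared per-run seeds (taken
#' from the first config), so rows differ only in the ablated factor, and
#' collects one result row per config.
#'
#' @param documents,schema,backends As for [run_pipeline()].
#' @param configs Non-empty list of [ablation_config()]s.
#' @return An object of class `ablation_grid`: `table` (data frame
#'   `label`, `metric`, `mean`, `sd`, `n`) and `results` (named list of
#'   `pipeline_result`s).
#' @export
run_ablation_grid <- function(documents, schema, configs, backends) {
  if (length(configs) == 0L) abort("`configs` must be non-empty")
  seeds <- configs[[1L]]$seeds
  results <- list()
  rows <- list()
  for (cfg in configs) {
    cfg$seeds <- seeds[seq_len(cfg$n_runs)]
    res <- run_pipeline(documents, schema, cfg, backends)
    results[[cfg$label]] <- res
    m <- res$aggregate$metrics
    rows[[length(rows) + 1L]] <- data.frame(label = cfg$label,
                                            metric = m$metric,
                                            mean = m$mean, sd = m$sd,
                                            n = res$aggregate$n,
                                            stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), results = results),
            class = "ablation_grid")
}

#' @export
print.ablation_grid <- function(x, ...) {
  cat("<ablation_grid>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write audit logs and result tables
#'
#' The audit log is JSON lines, one record per instance (question, pmids,
#' chosen chunk ids, prompt hash, per-run raw outputs and parsed labels);
#' the results table is a TSV of (label, metric, mean, sd, n). Both
#' writers are deterministic, so equal runs produce byte-identical files.
#'
#' @param result A `pipeline_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(result, path) {
  if (!inherits(result, "pipeline_result")) abort("`result` must be a pipeline_result")
  lines <- vapply(result$audit, function(rec) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_audit_log
#' @param x A `pipeline_result` or `ablation_grid`.
#' @export
write_results_table <- function(x, path) {
  tab <- if (inherits(x, "ablation_grid")) {
    x$table
  } else if (inherits(x, "pipeline_result")) {
    m <- x$aggregate$metrics
    data.frame(label = x$label, metric = m$metric, mean = m$mean, sd = m$sd,
               n = x$aggregate$n, stringsAsFactors = FALSE)
  } else {
    abort("`x` must be a pipeline_result or ablation_grid")
  }
  tab$mean <- sprintf("%.6f", tab$mean)
  tab$sd <- sprintf("%.6f", tab$sd)
  write_tsv(tab, path)
}
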