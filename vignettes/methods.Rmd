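---
title: "Methods: retrieval-augmented, chain-of-thought relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrieval-augmented, chain-of-thought relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragre)
```

## The model

`ragre` treats binary document-level relation extraction as question
answering. For a document with typed entities, every directed
(head-type, tail-type) pair is a candidate instance; the schema's template
turns it into a yes/no question (`Does chemical {head} induce disease
{tail}?`). A generator — in production a large language model, here a
pluggable backend — answers the question given the document, optionally
grounded with retrieved literature text and guided by task-specific
reasoning steps, under a constrained output protocol (`"My answer is:
Yes/No"`). Precision, recall and F1 over all instances, aggregated as
mean ± sample standard deviation over repeated runs, summarize a
configuration.

Three assumptions are built in. First, tasks are binary and directed:
schemas fix head → tail polarity (chemical → disease, gene → disease,
drug → adverse event) and no reverse pairs are enumerated. Second, the
positive class is "relation present", so an all-pairs enumeration scores a
pair positive iff a gold positive label exists for it. Third, the
generator is exchangeable: nothing in the pipeline depends on which
backend answers, only on the generator contract (a pure
`complete(prompt, config)` for the shipped mocks).

## Knowledge corpus construction

Entities resolve to controlled vocabulary terms through a two-column
mapping table, falling back to an entity's official symbol when no mapped
term exists (the convention for genes), and erroring otherwise — silent
misses would silently degrade retrieval. Article selection follows an
explicit co-occurrence rule: all articles whose title or abstract mentions
both terms, truncated to the **10** best by the service's relevance
ranking when more exist; if none co-mention the terms, the **5**
best-ranked articles of each single-term query are merged, first entity's
list first, duplicates collapsed to their first occurrence. The merge
order is fixed for determinism. Offline, relevance ranking is an explicit
`rank` column in the store's query index; a live adapter would request
relevance-sorted results and cache responses into the same store format.
Transport concerns (retries, rate limits) belong to live adapters and are
out of scope here.

## Chunking

Each abstract paragraph is segmented three ways, and the union forms the
retrieval store:

* **paragraph** (tag `P`): the paragraph itself;
* **sentence** (tag `S`): a deterministic rule-based splitter — a run of
  `.!?` followed by whitespace and a capital or digit ends a sentence,
  unless the preceding token is a known abbreviation (`i.v.`, `e.g.`,
  `Fig.`, `No.`, ...). The rule set ships with the package so splitting is
  reproducible; no probabilistic tokenizer is involved. Splitting is
  lossless: the concatenated sentences reproduce the paragraph modulo
  whitespace;
* **window** (tag `W`): `k` consecutive sentences with stride `d`,
  defaults `k = 3`, `d = 2`. Windows start at sentences 1, 1+d, 1+2d, ...
  while a full window fits, so consecutive windows share `k − d`
  sentences (one at the defaults). If the final sentence would be
  uncovered, one end-anchored window of the last `k` sentences is
  appended, so the last window always ends at the last sentence and
  coverage is total. With at most `k` sentences the single full window is
  returned. For `N > k` the window count is `⌊(N−k)/d⌋ + 1`, plus one when
  the end-anchor fires. Setting `d = 1` reproduces the fully-overlapping
  stride-1 enumeration (`[s1,s2,s3], [s2,s3,s4], ...`); the generic
  stride-`d` definition with the `k = 3, d = 2` default was chosen because
  size and stride, not an enumeration, are the declared parameters, and
  the config reaches both behaviors.

Chunk ids are `pmid:TAG:index` (zero-padded); chunks with identical
normalized text (whitespace-collapsed, case-preserving — case can be
semantically meaningful in biomedical text) are deduplicated keeping the
lexicographically smallest id, and the store is sorted by id with C-locale
(radix) ordering. Rebuilds from equal inputs are therefore byte-identical,
and deduplication is idempotent.

## Retrieval

The question text — not the full query document — is the retrieval query:
the question already carries both entity surfaces, and embedding the whole
document would dilute them. The shipped encoder is a deterministic hashed
bag-of-words model: lower-cased alphanumeric tokens, FNV-1a-hashed into
`dim = 256` buckets, L2-normalized counts. It is not a semantic model and
is not meant to be; it satisfies the encoder contract (fixed dimension,
same text ⇒ same vector), is fast, needs no model download, and ranks
lexical-overlap matches highly — sufficient for planted-evidence fixtures
and for exercising every retrieval code path. A neural sentence encoder
plugs in through `text_encoder()` without touching the pipeline.
Similarity is plain cosine; selection takes the `count` most similar
chunks (or least similar, for the low-similarity ablation), ties broken by
ascending chunk id for determinism, `count = 0` for the no-knowledge
ablation. Embeddings are memoized per backend keyed by normalized text.

## Prompts, generation, parsing

Prompt sections are fixed in order: question; document (title +
passages); external-knowledge block (numbered retrieved chunks, when
any); reasoning steps (numbered CoT instructions with the entity surfaces
substituted, when enabled); for the zero-shot-CoT variant instead, the
bare cue `"Let's think step by step."`; and always, exactly once, the
output directive. Rendering is a pure function, so prompt bytes are stable
across runs — which is what makes cassette record/replay and audit-log
determinism possible.

CoT templates are static, editable per-task assets (two numbered steps per
task by default: define the relation concept, then decide it for the named
entities). The question slot is filled with each entity's *first mention*
surface form — a deterministic choice among a document's several mentions.

Parsing keys on the **last** case-insensitive occurrence of
`"My answer is:"`, because chain-of-thought reasoning may quote the
directive earlier in the completion; the first following word, lower-cased
and stripped of punctuation, must be `yes` or `no`. Anything else is
`unparseable`; unparseable completions default to the negative label *and*
are tallied separately, so recall is never silently inflated by parser
failures. The parser is total.

An `augmented` prompt requires at least one of a retrieved-chunk block or
a CoT template, rather than requiring CoT unconditionally: the ablation
grid needs the retrieval-only ("w/o CoT") and reasoning-only ("w/o RAG")
variants as first-class prompts.

## Evaluation and ablations

Metrics follow the standard binary definitions with the conservative
zero-denominator convention (P, R, F1 = 0 when undefined). Aggregation
uses the sample (n−1) standard deviation with `n_runs = 3` as default, and
sd = 0 for a single run. Ablation grids share per-run seeds across
configurations so rows differ only in the ablated factor, and every run
emits a per-instance audit record (question, selected PMIDs, chosen chunk
ids and similarities, a 32-bit prompt fingerprint, per-run raw output and
parsed label) serialized as JSON lines with a deterministic writer.

## The synthetic fixture suite

The generator emulates the structure the pipeline depends on, at desk
scale: 20 documents, 1–2 head and 1–3 tail entities each (~60 candidate
pairs), positive prevalence 0.5, a planted abstract per positive term pair
whose first sentence states the relation with both terms, a background
abstract per entity term (what the single-term fallback finds for negative
pairs), and 10 distractor abstracts of unrelated vocabulary. Whether a
relation holds is decided once per term pair and reused across documents —
a world-fact convention that keeps the store consistent with the labels
(a pair negative somewhere never has planted co-occurrence evidence).
Entity names are pronounceable synthetic tokens (e.g. `bexdarine`,
`cardneurosis`) disjoint from the distractor vocabulary. Generation is a
pure function of (config, seed); suites serialize to a plain-text
directory byte-identically.

What the fixtures do *not* emulate: real biomedical discourse (negation,
hedging, coreference), noisy entity normalization, abstracts where
co-mention does not imply the relation, and a semantic encoder's
generalization beyond lexical overlap. Passing tests therefore validate
the pipeline's mechanics, contracts and determinism — not benchmark-level
extraction quality, which requires the real corpora and a live generator
behind the same contracts.

The mock generators bracket the harness: the oracle mock must yield
exactly F1 = 1 with zero spread (any deviation is a harness bug); the
always-yes mock must show recall 1 and precision equal to prevalence
(contingency algebra); the knowledge-gated mock answers positives
correctly only with the planted sentence in the prompt and negatives only
with reasoning steps present, forcing the full configuration to dominate
both single-enhancement ablations.

## Numerical and degenerate-input choices

Tolerances are not needed anywhere in the core: all comparisons are exact
(counts, strings, rational arithmetic on small integers). Cosine
similarity clamps to `[−1, 1]` against floating-point drift and rejects
zero vectors rather than returning a conventional value. Empty hit lists
everywhere yield empty selections, not errors; a document lacking a
required entity type yields zero instances; `count` beyond the store size
returns the whole store with a warning. All string ordering uses C-locale
radix sorting so serialized artifacts do not depend on the session locale.

## Problem sizes

The shipped tests run the retrieval-vs-brute-force equivalence on 100
random stores of up to 200 chunks, the metric identities on 1000 random
prediction sets, the window laws exhaustively for N ≤ 30, k ≤ 5, d ≤ k,
and the end-to-end grids on the 20-document suite — sizes chosen so the
full suite completes in a couple of minutes on one CPU while still
exercising every branch.

## Known limitations

* The live literature-service and generator adapters are contract stubs by
  design; record/replay cassettes stand in for live traffic.
* The hashed encoder cannot retrieve paraphrased evidence; rankings are
  lexical.
* The sentence splitter's abbreviation list is finite; unlisted
  abbreviations followed by a capitalized word split a sentence early
  (chunk boundaries shift, nothing is lost).
* ADE-style corpora do not define negative-pair construction; negative
  sampling is available but off by default, and reported ADE metrics
  depend on that choice.
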