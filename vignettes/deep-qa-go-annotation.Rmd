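---
title: "Deep question answering over Gene Ontology annotations: methods"
author: "goqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep question answering over Gene Ontology annotations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Questions such as *"what molecular functions are affected by Aminophenols?"*
or *"what cellular component is the location of ARVCF?"* have answers that
are Gene Ontology (GO) concepts, not sentences. A conventional
question-answering engine retrieves abstracts and extracts answers that are
literally written in them. For functional annotation this fails in a
characteristic way: the correct GO term (say, *protein serine/threonine
kinase activity*) is rarely spelled out in any abstract about the protein.
The answer exists in no corpus; it exists in curators' heads and, crucially,
in curated databases.

`goqa` implements and contrasts the two answer-extraction strategies inside
one retrieval-and-aggregation pipeline:

* a **dictionary classifier**: a vector-space engine that indexes every GO
  term's name and synonyms as a pseudo-document and ranks terms by BM25
  similarity to the abstract, plus a literal pattern matcher that boosts
  terms whose surface form occurs verbatim in the text;
* a **supervised k-NN classifier**: retrieve the *k* curated abstracts most
  lexically similar to the input (BM25 again), and let them vote with the GO
  terms curators assigned to them. Because the vote carries curated
  knowledge, this classifier can output terms present in no text — "deep"
  question answering.

## The pipeline

For a question the pipeline runs four stages:

1. **Question categorization.** A small template table maps question forms
   onto one GO axis (the *target set*: molecular_function,
   cellular_component or biological_process) and strips the scaffold,
   leaving the entity name as the retrieval query. Unknown question forms
   are an error by design: guessing a target set silently would produce
   confidently wrong answer lists.
2. **Retrieval.** An inverted index over the abstract corpus is searched
   with the entity query, in one of two modes: `bm25` (Okapi BM25,
   relevance-ordered) or `boolean_recency` (all query tokens required,
   newest first — the shape of a PubMed-style search). The first 100
   retrieved abstracts (default) continue.
3. **Micro-reading.** The pluggable classifier assigns up to `m = 5` GO
   terms of the target set to each retrieved abstract. The target-set
   filter is applied *before* the per-document cutoff so off-axis
   predictions never consume cutoff slots. Every retrieved PMID is excluded
   from the k-NN knowledge base while it is being read (leave-out), so a
   curated abstract can never vote for itself.
4. **Macro-reading.** Per-abstract prediction sets are aggregated by
   citation counting: a candidate answer's score is the number of retrieved
   abstracts whose prediction list contains it. Ranking is purely
   statistical — score descending, GO id ascending — and therefore invariant
   to document order.

## Scoring details and numerical choices

**BM25.** `score(q,d) = Σ_t idf(t) · tf(t,d)(k1+1) / (tf(t,d) +
k1(1−b+b·len(d)/avgdl))` summed over distinct query tokens, with
`idf(t) = ln(1 + (N−df+0.5)/(df+0.5))`. Defaults `k1 = 1.2`, `b = 0.75` are
the standard Okapi/Terrier operating point. The idf is kept non-negative
(the `+1` inside the log) so that on very small collections — term
pseudo-documents, toy corpora — a token present in most documents cannot
produce negative scores. Ties are always broken by ascending document id,
making every ranking reproducible.

**Normalization.** One normalizer is shared by the tokenizer, the ontology
surface forms and the literal matcher: Unicode NFKC, lowercase, punctuation
to spaces except hyphens and slashes (GO names contain
`serine/threonine`), whitespace collapsed. A small stoplist is applied
identically to indexed text and queries, but *not* to literal matching,
where names such as "regulation of transcription" must stay contiguous.
Stemming (a conservative three-rule plural stripper) is available but off
by default.

**Literal matching.** A term is "recognized" iff one of its normalized
surface forms occurs as a contiguous token subsequence of the normalized
text — no gaps, no reordering. This is the most conservative reading of
pattern matching; approximate or gapped matching would inflate dictionary
recall unpredictably.

**The boost.** The dictionary classifier's final score is
`vsm + B · match_length` with `B = 1 + max(vsm)` chosen per call. The boost
is deliberately *rank-dominant* rather than a tuned constant: every
literally recognized term outranks every unrecognized one, and longer
matches outrank shorter ones. Any finite additive constant would make the
dictionary/vector-space trade-off depend on corpus-specific score scales.

**k-NN voting.** Votes are raw neighbour counts ("most prevalent"), with
summed neighbour similarity and then GO id as tie-breaks;
similarity-weighted voting is available behind a flag. Zero-similarity
documents are never neighbours, and `k` (default 100) clamps to the
knowledge-base size. Excluding a PMID removes it from the neighbour pool
but deliberately does not rebuild the collection statistics (N, idf,
average length); holding the document out physically gives the same votes
but marginally different similarities, and tests compare against a
brute-force oracle that applies the same convention.

**GO levels.** The "level" of a term is the number of edges on the
*longest* is_a path from the namespace root (root = 0). In a DAG a term may
be reachable by paths of different lengths; the longest-path depth is the
only monotone choice (a child is always at least one level below its
deepest parent) and is the convention used when reporting how specific an
answer is. Only is_a edges participate. Published level figures depend on
the ontology release they were computed against, so exact level values are
documentation examples, not test targets.

**Evaluation.** Top precision `P0 = max_i |top_i ∩ gold|/i` (the
interpolated precision at recall 0) and recall at rank `r` are computed per
question and macro-averaged without weights. Matching is strict identifier
equality after alt-id resolution; a gold term's parent or child is wrong.
Questions with no answer list score 0 rather than being dropped, so macro
averages are comparable across systems. Significance of paired per-question
differences is assessed with a two-sided sign-flip randomization test
(`p = (1 + #extreme)/(1 + n_permutations)`, or exact enumeration up to 20
pairs); this choice of test is this package's own, standard for query-level
IR metrics.

## The synthetic data generator

Real-scale experiments require a GOA snapshot, a local MEDLINE copy and a
commercial third-party classifier. The generator replaces them with a world
whose statistical structure is controlled:

* **Ontology**: per namespace, a root plus `n_terms` terms wired by
  preferential attachment (well-connected terms attract more children),
  with unique multi-word names from a pronounceable syllable vocabulary,
  synonyms (word permutations plus one extra word), occasional alt ids and
  obsolete terms.
* **Curated corpus**: each term receives `docs_per_term` abstracts (default
  15, above the ~10-instances-per-class trainability rule of thumb); each
  abstract is annotated with 1–4 terms. Text mixes background tokens, each
  annotated term's private *topic tokens*, and — independently per
  annotation with probability `rho` — the term's literal name as a
  contiguous phrase.
* **Benchmark**: each of `n_questions` entities gets a gold set in one
  namespace and `docs_per_entity` fresh abstracts containing the entity
  token, the gold terms' topic tokens, literal gold names with probability
  `rho`, and `distractor_mentions` (default 3) literally mentioned
  *non-gold* terms of the same namespace. Entity abstracts are never in the
  knowledge base.

Three design points matter. First, name, topic, background and entity
vocabularies are pairwise disjoint by construction, so `rho` alone decides
whether the evidence for an annotation is explicit (its name is in the
text) or implicit (only its topic signal is). At `rho = 1` a dictionary
classifier sees every answer; at `rho = 0` it can see none, while lexical
similarity between abstracts still carries the signal a k-NN classifier
needs. Second, the distractor mentions model what retrieved literature
actually looks like: abstracts name many on-axis concepts that are not the
curated answer, and it is these literal-but-wrong candidates that cap
dictionary precision — published example outputs show dictionary top-10
lists dominated by exactly such terms. Without distractors a dictionary
pipeline would enjoy an unrealistically clean world in which any literal
match is correct. Third, one seed fixes everything: the three generators
draw from seeds `seed`, `seed+1`, `seed+2` in documented order, so every
corpus, benchmark and downstream ranking is bit-reproducible.

What the generator does **not** emulate: real biomedical language
(morphology, abbreviations, paraphrase), annotation sparsity skew, ontology
depth distributions, or retrieval noise from millions of off-topic
documents. Passing tests therefore demonstrate that the machinery is
correct and that the explicit/implicit contrast behaves as theorized, not
that any particular performance level transfers to MEDLINE.

## The reference experiment

The package's own headline experiment (also recomputed by
`scripts/acceptance.R`) runs at `rho = 0.1`, 30 questions, 20 abstracts per
entity, 15 curated abstracts per term, 50 terms per namespace — about 2 850
abstracts and 153 terms, sized so the complete run takes seconds on one
core while leaving every effect visible. Under these conditions the k-NN
pipeline's macro P0 and recall@5 are several times the dictionary
pipeline's (both at least doubled, a contrast robust across seeds), the
dictionary classifier is near-perfect at `rho = 1` and near-zero at
`rho = 0`, and swapping BM25 retrieval for boolean/recency retrieval moves
macro P0 by (numerically) zero — on this benchmark each entity tags fewer
documents than the retrieval cap, so both modes retrieve the same set in
different order, and citation counting is order-invariant. The last
observation is the small-world analogue of the finding that the choice of
search engine matters far less than the answer-extraction strategy.

## Limitations

* The question categorizer is a template table; free-form questions outside
  the three supported shapes are rejected, not guessed.
* Dictionary matching is exact: no abbreviation expansion, variant
  generation or fuzzy matching.
* The k-NN classifier can only ever propose terms present in its knowledge
  base; terms never annotated are invisible to it (the stratified
  `recall_by_support()` report quantifies this).
* Live literature retrieval is out of scope; the corpus is local by design,
  with the retrieval mode flag as the seam where a remote engine would
  plug in.
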