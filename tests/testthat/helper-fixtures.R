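# Hand-written fixtures and shared (cached) synthetic worlds.

tiny_obo <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: molecular root",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: catalytic activity",
    "namespace: molecular_function",
    "alt_id: GO:1111111",
    "synonym: \"Catalytic  Activity\" EXACT []",
    "synonym: \"enzyme activity\" RELATED []",
    "is_a: GO:0000001 ! molecular root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: nitrile hydratase activity",
    "namespace: molecular_function",
    "is_a: GO:0000002 ! catalytic activity",
    "is_a: GO:0000001 ! molecular root",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: retired function",
    "namespace: molecular_function",
    "is_obsolete: true",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: component root",
    "namespace: cellular_component",
    "",
    "[Term]",
    "id: GO:0000006",
    "name: nucleus",
    "namespace: cellular_component",
    "is_a: GO:0000005 ! component root",
    "")
}

tiny_ontology <- function() parse_obo(tiny_obo())

gaf_line <- function(pmid, go, evidence, qualifier = "", ref = NULL) {
  if (is.null(ref)) ref <- paste0("PMID:", pmid)
  paste("DB", paste0("OBJ:", pmid), "SYM", qualifier, go, ref, evidence,
        "", "F", "", "", "protein", "taxon:0000", "20120801", "DB", "", "",
        sep = "\t")
}

make_tiny_corpus <- function(texts, pmids = as.character(seq_along(texts)),
                             dates = NULL) {
  df <- data.frame(pmid = pmids, title = "", text = texts,
                   stringsAsFactors = FALSE)
  if (!is.null(dates)) df$date <- as.Date(dates)
  as_corpus(df)
}

# Shared worlds are built once per test run and cached; every consumer uses
# the same fixed seeds so results are reproducible.
.goqa_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.goqa_cache[[key]])) .goqa_cache[[key]] <- force(expr)
  .goqa_cache[[key]]
}

# The reference deep-QA study condition: implicit answers (rho = 0.1),
# 30 questions, 20 retrievable abstracts each, 15 curated abstracts per term.
qa_world <- function() {
  cached("qa_world", {
    cfg <- synth_config(seed = 42, rho = 0.1, n_terms = 50, docs_per_term = 15,
                        n_questions = 30, docs_per_entity = 20)
    ont <- make_ontology(cfg)
    cw <- make_corpus(cfg, ont)
    qa <- make_qa_benchmark(cfg, ont, cw$corpus)
    list(cfg = cfg, ontology = ont, kb = cw$kb, corpus = qa$corpus,
         benchmark = qa$benchmark, entity_pmids = qa$entity_pmids,
         index = build_index(qa$corpus),
         term_index = build_term_index(ont),
         kb_index = build_kb_index(cw$kb, cw$corpus))
  })
}

qa_answers_knn <- function() {
  w <- qa_world()
  cached("ans_knn", run_benchmark(w$benchmark, w$index, w$kb_index, w$ontology))
}

qa_answers_dict <- function() {
  w <- qa_world()
  cached("ans_dict", run_benchmark(w$benchmark, w$index, w$term_index, w$ontology))
}

qa_answers_knn_boolean <- function() {
  w <- qa_world()
  cached("ans_knn_bool",
         run_benchmark(w$benchmark, w$index, w$kb_index, w$ontology,
                       params = retrieval_params(mode = "boolean_recency")))
}

# Fully explicit regime: every annotation's name is literally in the text.
explicit_micro_world <- function() {
  cached("explicit_micro", {
    cfg <- synth_config(seed = 42, rho = 1, n_terms = 10, docs_per_term = 10,
                        n_questions = 2)
    ont <- make_ontology(cfg)
    cw <- make_corpus(cfg, ont)
    list(cfg = cfg, ontology = ont, kb = cw$kb, corpus = cw$corpus,
         term_index = build_term_index(ont))
  })
}

# Fully implicit regime: no annotation name ever appears in any text.
implicit_micro_world <- function() {
  cached("implicit_micro", {
    cfg <- synth_config(seed = 42, rho = 0, n_terms = 8, docs_per_term = 12,
                        n_questions = 2)
    ont <- make_ontology(cfg)
    cw <- make_corpus(cfg, ont)
    list(cfg = cfg, ontology = ont, kb = cw$kb, corpus = cw$corpus,
         term_index = build_term_index(ont),
         kb_index = build_kb_index(cw$kb, cw$corpus))
  })
}
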