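## Synthetic ontology / corpus / knowledge base / benchmark generator.
##
## Emulates the study conditions of literature-based GO annotation with
## controlled statistical structure. Three token pools are disjoint by
## construction: term-name words (pronounceable syllable words), per-term
## topic tokens ("t0042"), and background tokens ("b017"); entity tokens
## ("prot07") form a fourth pool. Because topic tokens never overlap name
## tokens, the literal-mention probability `rho` cleanly separates explicit
## evidence (the term's name is in the text — what a dictionary classifier
## can see) from implicit evidence (only topic tokens — recoverable only by
## a supervised classifier voting over curated annotations).

#' Configuration for the synthetic generators
#'
#' Defaults describe the reference study condition used throughout the
#' package's own experiments: 50 terms per namespace, 15 curated abstracts
#' per term (comfortably above the ~10-instances-per-class trainability rule
#' of thumb), a literal-mention probability of 0.1 (answers are almost never
#' spelled out, the deep-QA regime), 30 questions with 20 retrievable
#' abstracts each, and 3 literally mentioned but non-gold distractor terms
#' per benchmark abstract (retrieved abstracts discuss many on-axis concepts
#' beyond the curated answers, which is what limits dictionary precision in
#' practice).
#'
#' @param seed Integer; fixes every downstream draw. The three generators
#'   consume seeds `seed`, `seed + 1`, `seed + 2` in that order.
#' @param n_terms Non-root terms per namespace.
#' @param branching Maximum is_a parents per term (preferential attachment).
#' @param synonyms_per_term Synonyms generated per term.
#' @param topic_tokens_per_term Private topic tokens per term.
#' @param background_vocab Background vocabulary size.
#' @param background_tokens_per_doc Background tokens drawn per document.
#' @param rho Probability, per annotation, that the term's literal name is
#'   inserted into the document text.
#' @param docs_per_term Curated abstracts generated per term.
#' @param extra_annotations_max Up to this many additional terms co-annotate
#'   each abstract (so 1 to `1 + extra_annotations_max` terms per abstract).
#' @param n_questions Benchmark questions.
#' @param gold_per_question Length-2 integer range for gold-set sizes.
#' @param docs_per_entity New abstracts tagged with each question's entity.
#' @param distractor_mentions Literally mentioned non-gold same-namespace
#'   terms per benchmark abstract.
#' @param alt_id_prob Probability a term carries a secondary (alt) id.
#' @param n_obsolete Obsolete terms per namespace.
#' @param year_range Publication-date range (uniform).
#' @return A validated `goqa_synth_config`.
#' @export
synth_config <- function(seed = 1L, n_terms = 50L, branching = 2L,
                         synonyms_per_term = 2L, topic_tokens_per_term = 5L,
                         background_vocab = 200L,
                         background_tokens_per_doc = 25L, rho = 0.1,
                         docs_per_term = 15L, extra_annotations_max = 3L,
                         n_questions = 30L, gold_per_question = c(1L, 3L),
                         docs_per_entity = 20L, distractor_mentions = 3L,
                         alt_id_prob = 0.1, n_obsolete = 1L,
                         year_range = c(2000L, 2014L)) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              branching = as.integer(branching),
              synonyms_per_term = as.integer(synonyms_per_term),
              topic_tokens_per_term = as.integer(topic_tokens_per_term),
              background_vocab = as.integer(background_vocab),
              background_tokens_per_doc = as.integer(background_tokens_per_doc),
              rho = rho, docs_per_term = as.integer(docs_per_term),
              extra_annotations_max = as.integer(extra_annotations_max),
              n_questions = as.integer(n_questions),
              gold_per_question = as.integer(gold_per_question),
              docs_per_entity = as.integer(docs_per_entity),
              distractor_mentions = as.integer(distractor_mentions),
              alt_id_prob = alt_id_prob, n_obsolete = as.integer(n_obsolete),
              year_range = as.integer(year_range))
  stopifnot(cfg$n_terms >= 1, cfg$branching >= 1, cfg$synonyms_per_term >= 0,
            cfg$topic_tokens_per_term >= 1, cfg$background_vocab >= 1,
            cfg$background_tokens_per_doc >= 1, cfg$rho >= 0, cfg$rho <= 1,
            cfg$docs_per_term >= 1, cfg$extra_annotations_max >= 0,
            cfg$n_questions >= 1, length(cfg$gold_per_question) == 2L,
            cfg$gold_per_question[1] >= 1,
            cfg$gold_per_question[2] >= cfg$gold_per_question[1],
            cfg$docs_per_entity >= 1, cfg$distractor_mentions >= 0,
            cfg$alt_id_prob >= 0, cfg$alt_id_prob <= 1, cfg$n_obsolete >= 0)
  structure(cfg, class = "goqa_synth_config")
}

# Pronounceable unique pseudo-words for term names (letters only, so they
# can never collide with the digit-bearing topic/background/entity tokens).
make_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  words <- character(0)
  while (length(words) < n) {
    cand <- matrix(sample(syl, 3L * max(n, 32L), replace = TRUE), ncol = 3L)
    cand <- paste0(cand[, 1L], cand[, 2L], cand[, 3L])
    words <- unique(c(words, cand))
  }
  words[seq_len(n)]
}

#' Generate a toy GO-style ontology
#'
#' Per namespace: one root plus `n_terms` terms wired into a random DAG by
#' preferential attachment (well-connected terms attract more children, as
#' in real ontologies), plus `n_obsolete` obsolete terms. Every term gets a
#' unique multi-word name, `synonyms_per_term` synonyms (word permutations
#' with one extra word), and with probability `alt_id_prob` a secondary id.
#' Each non-root term is also assigned private topic tokens (stored in the
#' `goqa_topics` attribute) that the corpus generator uses as the term's
#' implicit textual signal.
#'
#' @param config A [synth_config()].
#' @return A `goqa_ontology` with attribute `goqa_topics` (named list
#'   id -> topic tokens). Writable with [write_obo()].
#' @export
make_ontology <- function(config) {
  with_seed(config$seed, {
    per_ns <- 1L + config$n_terms + config$n_obsolete
    pool <- make_words(3L * per_ns * (3L + config$synonyms_per_term) + 50L)
    wi <- 0L
    id_counter <- 0L
    alt_counter <- 0L
    topic_counter <- 0L
    scopes_pool <- c("EXACT", "RELATED", "NARROW", "BROAD")
    terms <- list()
    topics <- list()
    for (ns in GO_NAMESPACES) {
      id_counter <- id_counter + 1L
      root_id <- sprintf("GO:%07d", id_counter)
      terms[[root_id]] <- list(
        id = root_id, name = paste(pool[wi + 1:2], collapse = " "),
        namespace = ns, synonyms = character(0), synonym_scopes = character(0),
        parents = character(0), alt_ids = character(0), obsolete = FALSE
      )
      wi <- wi + 2L
      ns_ids <- root_id
      child_counts <- 0L
      for (i in seq_len(config$n_terms)) {
        id_counter <- id_counter + 1L
        id <- sprintf("GO:%07d", id_counter)
        nlen <- sample(2:3, 1L)
        name_words <- pool[wi + seq_len(nlen)]
        wi <- wi + nlen
        name <- paste(name_words, collapse = " ")
        syns <- character(0)
        for (s in seq_len(config$synonyms_per_term)) {
          extra <- pool[wi + 1L]
          wi <- wi + 1L
          syns <- c(syns, paste(c(sample(name_words), extra), collapse = " "))
        }
        npar <- min(sample(seq_len(config$branching), 1L), length(ns_ids))
        pick <- sample.int(length(ns_ids), npar, prob = 1 + child_counts)
        parents <- ns_ids[pick]
        child_counts[pick] <- child_counts[pick] + 1L
        alt <- if (stats::runif(1) < config$alt_id_prob) {
          alt_counter <- alt_counter + 1L
          sprintf("GO:%07d", 1000000L + alt_counter)
        } else character(0)
        terms[[id]] <- list(
          id = id, name = name, namespace = ns, synonyms = syns,
          synonym_scopes = sample(scopes_pool, length(syns), replace = TRUE),
          parents = parents, alt_ids = alt, obsolete = FALSE
        )
        topics[[id]] <- sprintf("t%04d", topic_counter + seq_len(config$topic_tokens_per_term))
        topic_counter <- topic_counter + config$topic_tokens_per_term
        ns_ids <- c(ns_ids, id)
        child_counts <- c(child_counts, 0L)
      }
      for (j in seq_len(config$n_obsolete)) {
        id_counter <- id_counter + 1L
        id <- sprintf("GO:%07d", id_counter)
        terms[[id]] <- list(
          id = id, name = paste(pool[wi + 1:2], collapse = " "),
          namespace = ns, synonyms = character(0),
          synonym_scopes = character(0), parents = character(0),
          alt_ids = character(0), obsolete = TRUE
        )
        wi <- wi + 2L
      }
    }
    ont <- new_ontology(terms)
    attr(ont, "goqa_topics") <- topics
    ont
  })
}

random_dates <- function(n, year_range) {
  lo <- as.integer(as.Date(sprintf("%d-01-01", year_range[1])))
  hi <- as.integer(as.Date(sprintf("%d-12-31", year_range[2])))
  as.Date(sample(lo:hi, n, replace = TRUE), origin = "1970-01-01")
}

# One synthetic abstract: background chunks + each annotated/gold term's
# topic tokens + (with probability rho, per term) the term's literal name as
# one contiguous chunk + optional always-literal distractor names + optional
# entity token. Chunk order is shuffled; name chunks stay contiguous.
synth_doc_text <- function(config, ontology, topics, bg, terms_in,
                           entity = NULL, distractors = character(0)) {
  chunks <- as.list(sample(bg, config$background_tokens_per_doc, replace = TRUE))
  for (a in terms_in) {
    chunks <- c(chunks, as.list(topics[[a]]))
    if (stats::runif(1) < config$rho) {
      chunks <- c(chunks,
                  list(strsplit(normalize_text(ontology$terms[[a]]$name), " ")[[1L]]))
    }
  }
  for (d in distractors) {
    chunks <- c(chunks,
                list(strsplit(normalize_text(ontology$terms[[d]]$name), " ")[[1L]]))
  }
  if (!is.null(entity)) chunks <- c(chunks, list(entity))
  paste(unlist(chunks[sample.int(length(chunks))]), collapse = " ")
}

#' Generate a curated corpus and knowledge base
#'
#' Every annotatable (non-root, non-obsolete) term receives `docs_per_term`
#' abstracts; each abstract is annotated with that term plus up to
#' `extra_annotations_max` other terms. Abstract text mixes background
#' tokens, every annotated term's topic tokens, and — independently per
#' annotation with probability `rho` — the term's literal name as a
#' contiguous phrase. Titles are background-only. Dates are uniform over
#' `year_range`.
#'
#' @param config A [synth_config()].
#' @param ontology An ontology from [make_ontology()] (needs the
#'   `goqa_topics` attribute).
#' @return List with `corpus` (a `goqa_corpus`) and `kb` (a `goqa_kb`,
#'   evidence code `EXP`). Writable with [write_documents()] /
#'   [write_gaf()].
#' @export
make_corpus <- function(config, ontology) {
  topics <- attr(ontology, "goqa_topics")
  if (is.null(topics)) stop("ontology lacks the goqa_topics attribute; use make_ontology()")
  with_seed(config$seed + 1L, {
    annotatable <- names(topics)
    bg <- sprintf("b%03d", seq_len(config$background_vocab))
    n_docs <- length(annotatable) * config$docs_per_term
    pmid <- character(n_docs); title <- character(n_docs); text <- character(n_docs)
    ann_pmid <- character(0); ann_go <- character(0)
    di <- 0L
    for (t in annotatable) {
      for (j in seq_len(config$docs_per_term)) {
        di <- di + 1L
        pmid[di] <- as.character(1000000L + di)
        n_extra <- sample(0:config$extra_annotations_max, 1L)
        extras <- if (n_extra > 0L) sample(setdiff(annotatable, t), n_extra) else character(0)
        ann <- c(t, extras)
        text[di] <- synth_doc_text(config, ontology, topics, bg, ann)
        title[di] <- paste(sample(bg, 3L, replace = TRUE), collapse = " ")
        ann_pmid <- c(ann_pmid, rep(pmid[di], length(ann)))
        ann_go <- c(ann_go, ann)
      }
    }
    corpus <- as_corpus(data.frame(pmid = pmid, title = title, text = text,
                                   stringsAsFactors = FALSE))
    corpus$date <- random_dates(n_docs, config$year_range)
    list(corpus = corpus,
         kb = new_kb(ann_pmid, ann_go, rep("EXP", length(ann_go))))
  })
}

#' Generate a question benchmark and its retrievable abstracts
#'
#' `n_questions` entities, alternating between the molecular-function and
#' cellular-component axes. Each entity gets a gold set drawn from one
#' namespace and `docs_per_entity` new abstracts containing the entity
#' token, the gold terms' topic tokens, literal gold names with probability
#' `rho`, and `distractor_mentions` literally mentioned non-gold terms of
#' the same namespace. The new abstracts are appended to the corpus but NOT
#' to the knowledge base (they are the documents to be classified).
#' Questions are rendered with the two standard templates understood by
#' [categorize_question()].
#'
#' @param config A [synth_config()].
#' @param ontology An ontology from [make_ontology()].
#' @param corpus The corpus from [make_corpus()].
#' @return List with `benchmark` (a `goqa_benchmark`), `corpus` (the
#'   extended `goqa_corpus`) and `entity_pmids` (named list entity -> new
#'   pmids).
#' @export
make_qa_benchmark <- function(config, ontology, corpus) {
  topics <- attr(ontology, "goqa_topics")
  if (is.null(topics)) stop("ontology lacks the goqa_topics attribute; use make_ontology()")
  with_seed(config$seed + 2L, {
    annotatable <- names(topics)
    bg <- sprintf("b%03d", seq_len(config$background_vocab))
    ns_seq <- rep(c("molecular_function", "cellular_component"),
                  length.out = config$n_questions)
    question <- character(config$n_questions)
    entity <- character(config$n_questions)
    gold <- vector("list", config$n_questions)
    entity_pmids <- list()
    pmid <- character(0); title <- character(0); text <- character(0)
    pcounter <- 2000000L
    for (qi in seq_len(config$n_questions)) {
      ns <- ns_seq[qi]
      ent <- sprintf("prot%02d", qi)
      ns_pool <- intersect(annotatable, namespace_terms(ontology, ns))
      gsize <- sample(config$gold_per_question[1]:config$gold_per_question[2], 1L)
      if (gsize > length(ns_pool)) {
        stop("gold-set size ", gsize, " exceeds the ", length(ns_pool),
             " annotatable terms of namespace ", ns)
      }
      g <- sort(sample(ns_pool, gsize))
      pm <- character(config$docs_per_entity)
      for (d in seq_len(config$docs_per_entity)) {
        pcounter <- pcounter + 1L
        pm[d] <- as.character(pcounter)
        n_dis <- min(config$distractor_mentions, length(ns_pool) - gsize)
        dis <- if (n_dis > 0L) sample(setdiff(ns_pool, g), n_dis) else character(0)
        text <- c(text, synth_doc_text(config, ontology, topics, bg, g,
                                       entity = ent, distractors = dis))
        title <- c(title, paste(ent, paste(sample(bg, 2L, replace = TRUE),
                                           collapse = " ")))
        pmid <- c(pmid, pm[d])
      }
      entity_pmids[[ent]] <- pm
      entity[qi] <- ent
      gold[[qi]] <- g
      question[qi] <- if (ns == "molecular_function") {
        sprintf("what molecular functions are affected by %s ?", ent)
      } else {
        sprintf("what cellular component is the location of %s?", ent)
      }
    }
    new_docs <- data.frame(pmid = pmid, title = title, text = text,
                           stringsAsFactors = FALSE)
    new_docs$date <- random_dates(nrow(new_docs), config$year_range)
    extended <- rbind(as.data.frame(corpus), new_docs)
    list(benchmark = new_benchmark(question, entity, ns_seq, gold),
         corpus = as_corpus(extended),
         entity_pmids = entity_pmids)
  })
}
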