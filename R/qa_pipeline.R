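## End-to-end question answering.
##
## A question is categorized onto one GO axis (the target set) and reduced
## to an entity query; the IR component retrieves abstracts; a pluggable
## classifier micro-reads each abstract; macro-reading aggregates the
## per-abstract predictions by counting, for every candidate term, the
## number of citations that predicted it. The most cited concepts are the
## best answers.

#' Default question templates
#'
#' A small extensible rule table mapping question forms to GO namespaces.
#' Each row is a case-insensitive regular expression with one capture group
#' (the entity). Unsupported question forms fail loudly rather than
#' guessing.
#'
#' @return data.frame with columns `pattern`, `namespace`.
#' @export
default_question_templates <- function() {
  data.frame(
    pattern = c(
      "^\\s*what\\s+molecular\\s+functions?\\s+(?:is|are)\\s+(?:affected|associated|modulated)\\s+(?:by|with)\\s+(.+?)[\\s?]*$",
      "^\\s*what\\s+cellular\\s+components?\\s+(?:is|are)\\s+the\\s+locations?\\s+of\\s+(.+?)[\\s?]*$",
      "^\\s*what\\s+biological\\s+process(?:es)?\\s+(?:is|are)\\s+(?:affected|associated|regulated)\\s+(?:by|with)\\s+(.+?)[\\s?]*$"
    ),
    namespace = c("molecular_function", "cellular_component", "biological_process"),
    stringsAsFactors = FALSE
  )
}

#' Categorize a natural-language question
#'
#' Template matching identifies the target namespace and strips the question
#' scaffold, leaving the entity (the preferred name of the protein or
#' chemical) as the retrieval query.
#'
#' @param text Question string.
#' @param templates Rule table as in [default_question_templates()].
#' @return A `goqa_question`: list with `raw`, `entity_query`,
#'   `target_namespace`.
#' @export
categorize_question <- function(text, templates = default_question_templates()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  for (i in seq_len(nrow(templates))) {
    m <- regexec(templates$pattern[i], text, ignore.case = TRUE, perl = TRUE)
    g <- regmatches(text, m)[[1L]]
    if (length(g) == 2L) {
      entity <- trimws(gsub("[?!.]+$", "", g[[2L]]))
      if (!nzchar(entity)) next
      return(structure(
        list(raw = text, entity_query = entity,
             target_namespace = templates$namespace[i]),
        class = "goqa_question"
      ))
    }
  }
  stop("unsupported question form: '", text, "'")
}

#' @export
print.goqa_question <- function(x, ...) {
  cat("<goqa_question> '", x$raw, "' -> entity '", x$entity_query,
      "', target ", x$target_namespace, "\n", sep = "")
  invisible(x)
}

#' Aggregate per-document predictions into a ranked answer list
#'
#' Macro-reading: candidate terms are filtered to the target namespace, each
#' document's prediction list is treated as a set, and a term's score is the
#' number of documents (citations) whose list contains it. Answers are
#' ordered by score descending, GO id ascending; supporting pmids are
#' recorded. Invariant to the order of the input documents.
#'
#' @param predictions Named list (pmid -> character vector of GO ids, or a
#'   data.frame with a `go_id` column), one element per distinct document.
#' @param target_namespace The question's GO axis.
#' @param ontology A `goqa_ontology`.
#' @return A `goqa_answerset`: list with `answers` (data.frame `go_id`,
#'   `score`, `pmids` list column) and `n_docs_used`.
#' @export
macro_read <- function(predictions, target_namespace, ontology) {
  allowed <- namespace_terms(ontology, target_namespace)
  preds <- lapply(predictions, function(p) {
    ids <- if (is.data.frame(p)) p$go_id else p
    # secondary ids resolve before the target-set filter
    known <- ids %in% names(ontology$alt_map)
    ids[known] <- unname(ontology$alt_map[ids[known]])
    unique(intersect(ids, allowed))
  })
  pmids <- names(preds)
  if (is.null(pmids)) pmids <- as.character(seq_along(preds))
  go <- unlist(preds, use.names = FALSE)
  src <- rep.int(pmids, lengths(preds))
  if (!length(go)) {
    answers <- data.frame(go_id = character(0), score = integer(0),
                          stringsAsFactors = FALSE)
    answers$pmids <- list()
  } else {
    support <- split(src, go)
    answers <- data.frame(go_id = names(support),
                          score = lengths(support),
                          stringsAsFactors = FALSE)
    answers$pmids <- lapply(support, sort)
    answers <- answers[order(-answers$score, answers$go_id), , drop = FALSE]
    rownames(answers) <- NULL
  }
  structure(
    list(answers = answers, n_docs_used = length(preds),
         target_namespace = target_namespace),
    class = "goqa_answerset"
  )
}

#' @export
print.goqa_answerset <- function(x, n = 10L, ...) {
  q <- attr(x, "question")
  if (!is.null(q)) cat("Question: ", q$raw, "\n", sep = "")
  cat("<goqa_answerset> ", nrow(x$answers), " candidate answers from ",
      x$n_docs_used, " documents (", x$target_namespace, ")\n", sep = "")
  if (nrow(x$answers)) {
    top <- utils::head(x$answers, n)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %2d. %s  (citations: %d)\n", i, top$go_id[i], top$score[i]))
    }
  }
  invisible(x)
}

#' Answer a question end to end
#'
#' Categorize -> retrieve -> micro-read each retrieved abstract with the
#' classifier -> macro-read. The namespace filter is applied inside the
#' classifier, before its per-document `m` cutoff, so off-axis terms never
#' consume cutoff slots. All retrieved pmids are excluded from any
#' knowledge base during classification (leave-out), so a curated abstract
#' cannot vote for itself or its co-retrieved neighbours.
#'
#' @param question Question string or a `goqa_question`.
#' @param index A `goqa_index` over the abstract corpus.
#' @param classifier Any classifier accepted by [classify_document()].
#' @param ontology A `goqa_ontology`.
#' @param params A [retrieval_params()] object (100 retrieved documents by
#'   default).
#' @param m Per-document prediction-list size (default 5).
#' @param templates Question rule table.
#' @return A `goqa_answerset` with the question attached; empty (with a
#'   warning) when no document is retrieved.
#' @export
answer_question <- function(question, index, classifier, ontology,
                            params = retrieval_params(), m = 5L,
                            templates = default_question_templates()) {
  q <- if (inherits(question, "goqa_question")) question else
    categorize_question(question, templates)
  hits <- search_index(index, q$entity_query, params)
  allowed <- namespace_terms(ontology, q$target_namespace)
  if (!nrow(hits)) {
    warning("no documents retrieved for entity '", q$entity_query, "'")
    out <- macro_read(stats::setNames(list(), character(0)),
                      q$target_namespace, ontology)
    attr(out, "question") <- q
    return(out)
  }
  exclude <- hits$pmid
  idx <- match(hits$pmid, index$pmids)
  preds <- lapply(seq_len(nrow(hits)), function(i) {
    tryCatch(
      classify_document(classifier, index$texts[[idx[i]]], m = m,
                        allowed_ids = allowed, exclude_pmids = exclude)$go_id,
      error = function(e) character(0)
    )
  })
  names(preds) <- hits$pmid
  out <- macro_read(preds, q$target_namespace, ontology)
  attr(out, "question") <- q
  out
}

#' Run a whole question benchmark through the pipeline
#'
#' Uses each entry's `entity` and `namespace` columns directly (the
#' benchmark already encodes the categorizer's output), so arbitrary
#' question phrasings in a benchmark file cannot derail a batch run.
#'
#' @param benchmark A `goqa_benchmark`.
#' @param index,classifier,ontology,params,m As in [answer_question()].
#' @return List of `goqa_answerset`, one per benchmark entry.
#' @export
run_benchmark <- function(benchmark, index, classifier, ontology,
                          params = retrieval_params(), m = 5L) {
  lapply(seq_len(nrow(benchmark)), function(i) {
    q <- structure(
      list(raw = benchmark$question[i], entity_query = benchmark$entity[i],
           target_namespace = benchmark$namespace[i]),
      class = "goqa_question"
    )
    suppressWarnings(
      answer_question(q, index, classifier, ontology, params = params, m = m)
    )
  })
}

#' Write a ranked answer list as TSV
#'
#' Columns: rank, go_id, name, citations, pmids (semicolon-joined).
#'
#' @param answerset A `goqa_answerset`.
#' @param file Path or connection.
#' @param ontology A `goqa_ontology` (for term names).
#' @return `file`, invisibly.
#' @export
write_answers <- function(answerset, file, ontology) {
  a <- answerset$answers
  lines <- c(
    "rank\tgo_id\tname\tcitations\tpmids",
    if (nrow(a)) sprintf(
      "%d\t%s\t%s\t%d\t%s", seq_len(nrow(a)), a$go_id,
      vapply(a$go_id, function(g) ontology$terms[[g]]$name, ""),
      a$score, vapply(a$pmids, paste, "", collapse = ";")
    )
  )
  writeLines(lines, file)
  invisible(file)
}
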