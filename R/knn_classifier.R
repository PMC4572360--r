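## Supervised k-nearest-neighbour GO classifier.
##
## Assigns to an unseen abstract the GO terms that are most prevalent among
## the k most lexically similar abstracts of a curated knowledge base. This
## is the "deep" component of the QA system: its answers come from curation,
## not from the input text, so it can propose terms that are literally
## present in no retrieved document.

#' Build a k-NN classifier over a knowledge base
#'
#' Indexes exactly the knowledge-base abstracts found in the corpus; KB
#' pmids missing from the corpus are dropped with a warning.
#'
#' @param kb A `goqa_kb`.
#' @param corpus A `goqa_corpus` holding the KB abstracts.
#' @param k Default neighbour count (the classic setting is 100).
#' @param stopwords,stem Tokenizer settings.
#' @return A `goqa_kb_index`.
#' @export
build_kb_index <- function(kb, corpus, k = 100L,
                           stopwords = default_stopwords(), stem = FALSE) {
  stopifnot(k >= 1)
  pmids <- names(kb$annotations)
  present <- pmids %in% corpus$pmid
  if (!any(present)) stop("no knowledge-base abstract is present in the corpus")
  if (!all(present)) {
    warning(sum(!present), " knowledge-base pmid(s) missing from the corpus, dropped")
  }
  pmids <- pmids[present]
  sub <- corpus[match(pmids, corpus$pmid), , drop = FALSE]
  structure(
    list(index = build_index(as_corpus(sub), stopwords = stopwords, stem = stem),
         kb = kb, k = as.integer(k)),
    class = "goqa_kb_index"
  )
}

#' @export
print.goqa_kb_index <- function(x, ...) {
  cat("<goqa_kb_index> ", x$index$n_docs, " curated abstracts, k = ", x$k,
      "\n", sep = "")
  invisible(x)
}

#' k-NN classification of a text
#'
#' Retrieves the `k` knowledge-base abstracts most similar to the text under
#' BM25 (after removing `exclude_pmids`; zero-similarity documents are never
#' neighbours), then scores each candidate GO term by the number of
#' neighbours annotated with it. Ties are broken by the summed BM25
#' similarity of the supporting neighbours, then by GO id. If fewer than `k`
#' neighbours have positive similarity, the available ones are used.
#'
#' @param kb_index A `goqa_kb_index`.
#' @param text Input text; must tokenize to at least one token.
#' @param k Neighbour count (defaults to the index's `k`); clamped to the
#'   knowledge-base size.
#' @param m Maximum number of terms returned (default 5).
#' @param exclude_pmids Pmids removed from the neighbour pool (the leave-out
#'   protocol for documents that are themselves curated).
#' @param allowed_ids Optional candidate restriction (target set), applied
#'   before the `m` cutoff.
#' @param weighted If `TRUE`, votes are weighted by BM25 similarity instead
#'   of raw neighbour counts.
#' @return data.frame with columns `go_id`, `score`, `n_neighbors`,
#'   `sim_sum`, at most `m` rows, best first.
#' @export
classify_knn <- function(kb_index, text, k = kb_index$k, m = 5L,
                         exclude_pmids = NULL, allowed_ids = NULL,
                         weighted = FALSE) {
  stopifnot(k >= 1, m >= 1)
  pool <- setdiff(kb_index$index$pmids, exclude_pmids)
  if (!length(pool)) stop("knowledge base is empty after exclusion")
  res <- search_index(kb_index$index, text,
                      retrieval_params(n_retrieved = kb_index$index$n_docs))
  if (!is.null(exclude_pmids)) res <- res[!res$pmid %in% exclude_pmids, , drop = FALSE]
  nb <- utils::head(res, min(k, nrow(res)))
  empty <- data.frame(go_id = character(0), score = numeric(0),
                      n_neighbors = integer(0), sim_sum = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(nb)) return(empty)
  ann <- kb_index$kb$annotations[nb$pmid]
  go <- unlist(ann, use.names = FALSE)
  sim <- rep.int(nb$score, lengths(ann))
  votes <- rowsum(cbind(n = rep(1L, length(go)), sim = sim), go)
  out <- data.frame(go_id = rownames(votes),
                    n_neighbors = as.integer(votes[, "n"]),
                    sim_sum = as.numeric(votes[, "sim"]),
                    stringsAsFactors = FALSE)
  if (!is.null(allowed_ids)) out <- out[out$go_id %in% allowed_ids, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$score <- if (weighted) out$sim_sum else as.numeric(out$n_neighbors)
  out <- out[order(-out$score, -out$sim_sum, out$go_id), , drop = FALSE]
  out <- out[, c("go_id", "score", "n_neighbors", "sim_sum")]
  rownames(out) <- NULL
  utils::head(out, m)
}

#' Classify a document with any pluggable classifier
#'
#' The QA pipeline treats classifiers as interchangeable black boxes. Methods
#' exist for the dictionary classifier (`goqa_term_index`), the k-NN
#' classifier (`goqa_kb_index`), and plain functions with signature
#' `function(text, m, allowed_ids, exclude_pmids)` returning a data.frame
#' with a `go_id` column (the adapter seam for external classifiers).
#'
#' @param classifier A classifier object.
#' @param text Input text.
#' @param m Maximum number of terms.
#' @param allowed_ids Optional candidate restriction.
#' @param exclude_pmids Pmids to leave out of any knowledge base.
#' @param ... Passed to methods.
#' @return data.frame with at least a `go_id` column, best first.
#' @export
classify_document <- function(classifier, text, m = 5L, allowed_ids = NULL,
                              exclude_pmids = NULL, ...) {
  UseMethod("classify_document")
}

#' @rdname classify_document
#' @export
classify_document.goqa_term_index <- function(classifier, text, m = 5L,
                                              allowed_ids = NULL,
                                              exclude_pmids = NULL, ...) {
  classify_dictionary(classifier, text, m = m, allowed_ids = allowed_ids)
}

#' @rdname classify_document
#' @export
classify_document.goqa_kb_index <- function(classifier, text, m = 5L,
                                            allowed_ids = NULL,
                                            exclude_pmids = NULL, ...) {
  classify_knn(classifier, text, m = m, allowed_ids = allowed_ids,
               exclude_pmids = exclude_pmids, ...)
}

#' @rdname classify_document
#' @export
classify_document.function <- function(classifier, text, m = 5L,
                                       allowed_ids = NULL,
                                       exclude_pmids = NULL, ...) {
  classifier(text, m = m, allowed_ids = allowed_ids,
             exclude_pmids = exclude_pmids)
}
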