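## Inverted index and Okapi BM25 retrieval.
##
## The QA pipeline's IR component. Two document-ordering modes are provided:
## `bm25` (vector-space, relevance-ordered) and `boolean_recency` (documents
## containing every query token, newest first), a local stand-in for
## PubMed-style boolean search ordered by reverse time.

#' Retrieval parameters
#'
#' @param k1 BM25 term-frequency saturation (> 0).
#' @param b BM25 length normalization in \[0, 1\].
#' @param n_retrieved Maximum number of documents returned (>= 1); the QA
#'   pipeline feeds this many abstracts to answer extraction.
#' @param mode `"bm25"` or `"boolean_recency"`.
#' @return A `goqa_retrieval_params` list.
#' @export
retrieval_params <- function(k1 = 1.2, b = 0.75, n_retrieved = 100L,
                             mode = c("bm25", "boolean_recency")) {
  mode <- match.arg(mode)
  stopifnot(k1 > 0, b >= 0, b <= 1, n_retrieved >= 1)
  structure(list(k1 = k1, b = b, n_retrieved = n_retrieved, mode = mode),
            class = "goqa_retrieval_params")
}

#' Build an inverted index over a corpus
#'
#' Tokenizes `title + " " + text` of every document (abstract granularity)
#' and stores postings (token -> document, term frequency), document
#' lengths, dates and the raw text (so the QA pipeline can classify
#' retrieved documents). Deterministic given the corpus.
#'
#' @param corpus A `goqa_corpus` (non-empty).
#' @param stopwords,stem Tokenizer settings, recorded and reused for queries.
#' @return A `goqa_index`.
#' @export
build_index <- function(corpus, stopwords = default_stopwords(), stem = FALSE) {
  if (is.null(nrow(corpus)) || nrow(corpus) == 0L) stop("cannot index an empty corpus")
  full <- paste(corpus$title, corpus$text)
  toks <- tokenize_many(full, stopwords = stopwords, stem = stem)
  doc_len <- lengths(toks)
  doc_id <- rep.int(seq_along(toks), doc_len)
  tok <- unlist(toks, use.names = FALSE)
  if (length(tok)) {
    pair <- paste(tok, doc_id, sep = "\r")
    tt <- table(pair)
    parts <- strsplit(names(tt), "\r", fixed = TRUE)
    ptok <- vapply(parts, `[[`, "", 1L)
    pdoc <- as.integer(vapply(parts, `[[`, "", 2L))
    ptf <- as.integer(tt)
    ord <- order(ptok, pdoc)
    postings_doc <- split(pdoc[ord], ptok[ord])
    postings_tf <- split(ptf[ord], ptok[ord])
  } else {
    postings_doc <- postings_tf <- list()
  }
  dates <- if ("date" %in% names(corpus)) corpus$date else as.Date(rep(NA, nrow(corpus)))
  structure(
    list(postings_doc = postings_doc, postings_tf = postings_tf,
         doc_lengths = doc_len, avg_doc_length = mean(doc_len),
         n_docs = nrow(corpus), pmids = as.character(corpus$pmid),
         dates = dates, texts = full, stopwords = stopwords, stem = stem),
    class = "goqa_index"
  )
}

#' @export
print.goqa_index <- function(x, ...) {
  cat("<goqa_index> ", x$n_docs, " documents, ", length(x$postings_doc),
      " distinct tokens, avg length ", round(x$avg_doc_length, 1), "\n", sep = "")
  invisible(x)
}

#' Search an index
#'
#' In `bm25` mode, scores every matching document with Okapi BM25,
#' \deqn{score(q,d) = \sum_t idf(t) \frac{tf(t,d)(k_1+1)}{tf(t,d) + k_1(1-b+b\,len(d)/avgdl)}}
#' with \eqn{idf(t) = \ln(1 + (N - df + 0.5)/(df + 0.5))} (non-negative by
#' construction), summing over the distinct query tokens; results are ordered
#' by descending score, ties by ascending pmid. In `boolean_recency` mode,
#' returns the documents containing *all* query tokens, newest first (ties by
#' pmid); document dates are required. At most `n_retrieved` rows are
#' returned.
#'
#' @param index A `goqa_index`.
#' @param query_text Query string; must tokenize to at least one token under
#'   the index's tokenizer settings.
#' @param params A [retrieval_params()] object.
#' @return data.frame with columns `pmid` and `score` (BM25 score, or the
#'   numeric date in `boolean_recency` mode).
#' @export
search_index <- function(index, query_text, params = retrieval_params()) {
  qtok <- unique(tokenize(query_text, stopwords = index$stopwords, stem = index$stem))
  if (!length(qtok)) stop("query is empty after tokenization")
  if (params$mode == "bm25") {
    scores <- numeric(index$n_docs)
    for (t in qtok) {
      pd <- index$postings_doc[[t]]
      if (is.null(pd)) next
      tf <- index$postings_tf[[t]]
      df <- length(pd)
      idf <- log(1 + (index$n_docs - df + 0.5) / (df + 0.5))
      denom <- tf + params$k1 *
        (1 - params$b + params$b * index$doc_lengths[pd] / index$avg_doc_length)
      scores[pd] <- scores[pd] + idf * tf * (params$k1 + 1) / denom
    }
    hit <- which(scores > 0)
    hit <- hit[order(-scores[hit], index$pmids[hit])]
    hit <- utils::head(hit, params$n_retrieved)
    data.frame(pmid = index$pmids[hit], score = scores[hit],
               stringsAsFactors = FALSE)
  } else {
    if (all(is.na(index$dates))) {
      stop("boolean_recency mode requires document dates")
    }
    posts <- index$postings_doc[qtok]
    if (any(vapply(posts, is.null, TRUE))) {
      hit <- integer(0)
    } else {
      hit <- Reduce(intersect, posts)
    }
    if (length(hit) && anyNA(index$dates[hit])) {
      stop("boolean_recency mode: matched document(s) without a date")
    }
    hit <- hit[order(index$dates[hit], index$pmids[hit],
                     decreasing = c(TRUE, FALSE), method = "radix")]
    hit <- utils::head(hit, params$n_retrieved)
    data.frame(pmid = index$pmids[hit], score = as.numeric(index$dates[hit]),
               stringsAsFactors = FALSE)
  }
}
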