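## Dictionary-based GO classifier.
##
## Two components, mirroring classic thesaurus-based categorizers: (1) a
## vector-space engine that indexes every term's surface forms as one
## pseudo-document and ranks terms by BM25 similarity to the input text
## (high recall); (2) a literal pattern matcher that recognizes surface
## forms occurring verbatim in the text and boosts those terms above all
## purely vector-space matches (high precision).

#' Build a term index for the dictionary classifier
#'
#' One pseudo-document per non-obsolete term in the requested namespaces,
#' containing all the term's surface forms (name + synonyms, normalized).
#'
#' @param ontology A `goqa_ontology`.
#' @param namespaces Character vector of namespaces to index.
#' @param stopwords,stem Tokenizer settings for the vector-space component.
#' @return A `goqa_term_index`.
#' @export
build_term_index <- function(ontology, namespaces = GO_NAMESPACES,
                             stopwords = default_stopwords(), stem = FALSE) {
  if (!length(namespaces)) stop("at least one namespace is required")
  ids <- unlist(lapply(namespaces, function(ns) namespace_terms(ontology, ns)),
                use.names = FALSE)
  forms <- lapply(ids, function(id) surface_forms(ontology, id))
  pseudo <- as_corpus(data.frame(
    pmid = ids, title = "",
    text = vapply(forms, paste, "", collapse = " "),
    stringsAsFactors = FALSE
  ))
  structure(
    list(index = build_index(pseudo, stopwords = stopwords, stem = stem),
         go_ids = ids,
         forms = stats::setNames(forms, ids),
         max_form_len = max(1L, max(lengths(strsplit(unlist(forms), " ", fixed = TRUE))))),
    class = "goqa_term_index"
  )
}

#' @export
print.goqa_term_index <- function(x, ...) {
  cat("<goqa_term_index> ", length(x$go_ids), " terms, ",
      length(unlist(x$forms)), " surface forms\n", sep = "")
  invisible(x)
}

#' Vector-space ranking of ontology terms against a text
#'
#' Scores the input text (as a BM25 query) against every term
#' pseudo-document; all positive-scoring terms are returned in descending
#' score order (ties by GO id).
#'
#' @param term_index A `goqa_term_index`.
#' @param text Input text; must tokenize to at least one token.
#' @return data.frame with columns `go_id`, `score`.
#' @export
vsm_rank <- function(term_index, text) {
  res <- search_index(term_index$index, text,
                      retrieval_params(n_retrieved = length(term_index$go_ids)))
  data.frame(go_id = res$pmid, score = res$score, stringsAsFactors = FALSE)
}

#' Literal occurrences of term surface forms in a text
#'
#' A term matches iff one of its surface forms occurs as a contiguous token
#' subsequence of the normalized text (no gaps, no reordering; stopwords are
#' kept so multiword names stay contiguous). `match_length` is the token
#' count of the longest matching form.
#'
#' @param term_index A `goqa_term_index`.
#' @param text Input text.
#' @return data.frame with columns `go_id`, `match_length`.
#' @export
literal_matches <- function(term_index, text) {
  toks <- tokenize(text, stopwords = character(0), stem = FALSE)
  empty <- data.frame(go_id = character(0), match_length = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(toks)) return(empty)
  ngrams <- vector("list", term_index$max_form_len)
  for (L in seq_len(min(term_index$max_form_len, length(toks)))) {
    n <- length(toks) - L + 1L
    grams <- toks[seq_len(n)]
    if (L > 1L) {
      for (j in 2:L) grams <- paste(grams, toks[j:(n + j - 1L)])
    }
    ngrams[[L]] <- unique(grams)
  }
  ids <- character(0); lens <- integer(0)
  for (id in term_index$go_ids) {
    forms <- term_index$forms[[id]]
    flen <- lengths(strsplit(forms, " ", fixed = TRUE))
    hit <- vapply(seq_along(forms), function(i) {
      L <- flen[[i]]
      L <= length(toks) && forms[[i]] %in% ngrams[[L]]
    }, TRUE)
    if (any(hit)) {
      ids <- c(ids, id)
      lens <- c(lens, max(flen[hit]))
    }
  }
  data.frame(go_id = ids, match_length = lens, stringsAsFactors = FALSE)
}

#' Dictionary classification of a text
#'
#' Combines the two components: the final score is the BM25 vector-space
#' score plus `B * match_length` for literally matched terms, where the
#' boost `B` is chosen per call as one plus the maximum vector-space score.
#' This makes the boost rank-dominant: every literally recognized term
#' outranks every unmatched term, and among matched terms longer matches win.
#' Ties are broken by ascending GO id.
#'
#' @param term_index A `goqa_term_index`.
#' @param text Input text; must tokenize to at least one token.
#' @param m Maximum number of terms returned (default 5).
#' @param allowed_ids Optional character vector restricting candidates (the
#'   question's target set); applied before the `m` cutoff.
#' @return data.frame with columns `go_id`, `score`, `literal_match`,
#'   `match_length`, at most `m` rows, best first.
#' @export
classify_dictionary <- function(term_index, text, m = 5L, allowed_ids = NULL) {
  stopifnot(m >= 1)
  vsm <- vsm_rank(term_index, text)
  lit <- literal_matches(term_index, text)
  ids <- union(vsm$go_id, lit$go_id)
  if (!is.null(allowed_ids)) ids <- intersect(ids, allowed_ids)
  if (!length(ids)) {
    return(data.frame(go_id = character(0), score = numeric(0),
                      literal_match = logical(0), match_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  vscore <- vsm$score[match(ids, vsm$go_id)]
  vscore[is.na(vscore)] <- 0
  mlen <- lit$match_length[match(ids, lit$go_id)]
  mlen[is.na(mlen)] <- 0L
  boost <- 1 + max(vsm$score, 0)
  score <- vscore + boost * mlen
  out <- data.frame(go_id = ids, score = score, literal_match = mlen > 0L,
                    match_length = as.integer(mlen), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, m)
}
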