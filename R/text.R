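#' Default stopword list
#'
#' A small English stoplist applied identically to indexed documents and to
#' queries. Literal pattern matching against ontology term names never removes
#' stopwords (term names such as "regulation of transcription" contain them).
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "but", "by", "can",
    "do", "does", "for", "from", "had", "has", "have", "how", "in", "is",
    "it", "its", "may", "no", "not", "of", "on", "or", "our", "such", "that",
    "the", "their", "then", "there", "these", "this", "those", "to", "was",
    "we", "were", "what", "which", "who", "will", "with")
}

#' Normalize free text
#'
#' Lowercases, applies Unicode NFKC, replaces punctuation with spaces (keeping
#' hyphens and slashes, which occur inside GO names such as
#' "serine/threonine kinase"), and collapses whitespace. This is the single
#' normalization shared by the ontology surface forms, the tokenizer and the
#' literal matcher, so that all components compare text in the same space.
#'
#' @param x Character vector.
#' @return Character vector of normalized strings.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- tolower(x)
  x <- gsub("[^\\p{L}\\p{N}/-]+", " ", x, perl = TRUE)
  trimws(x)
}

#' Light plural stemmer
#'
#' The three-rule "S" stemmer: -ies -> -y, -es -> -e, trailing -s dropped
#' (never after -us/-ss). Conservative enough for biomedical tokens; off by
#' default throughout the package.
#'
#' @param tokens Character vector of tokens.
#' @return Stemmed tokens.
#' @export
s_stem <- function(tokens) {
  ies <- grepl("ies$", tokens) & !grepl("(eies|aies)$", tokens) & nchar(tokens) > 4
  tokens[ies] <- sub("ies$", "y", tokens[ies])
  es <- !ies & grepl("es$", tokens) & !grepl("(aes|ees|oes)$", tokens) & nchar(tokens) > 3
  tokens[es] <- sub("es$", "e", tokens[es])
  ss <- !ies & !es & grepl("s$", tokens) & !grepl("(us|ss)$", tokens) & nchar(tokens) > 3
  tokens[ss] <- sub("s$", "", tokens[ss])
  tokens
}

#' Tokenize text
#'
#' Normalizes with [normalize_text()], splits on whitespace, removes
#' stopwords and optionally applies [s_stem()]. Queries and indexed documents
#' must be tokenized with the same settings; [build_index()] records its
#' settings and reuses them at query time.
#'
#' @param text A single character string.
#' @param stopwords Character vector of stopwords to drop; use `character(0)`
#'   to keep everything (as the literal matcher does).
#' @param stem Apply the S-stemmer?
#' @return Character vector of tokens (empty for empty text).
#' @export
tokenize <- function(text, stopwords = default_stopwords(), stem = FALSE) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  tokenize_many(text, stopwords = stopwords, stem = stem)[[1L]]
}

# Vectorized tokenizer used by the index builder.
tokenize_many <- function(texts, stopwords = default_stopwords(), stem = FALSE) {
  norm <- normalize_text(texts)
  toks <- strsplit(norm, " ", fixed = TRUE)
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (length(stopwords)) tk <- tk[!tk %in% stopwords]
    if (stem) tk <- s_stem(tk)
    tk
  })
}

# Accept a path, connection or in-memory character vector of lines.
input_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (length(x) > 1L) return(x)
  if (!grepl("\n", x, fixed = TRUE) && file.exists(x)) return(readLines(x, warn = FALSE))
  strsplit(x, "\n", fixed = TRUE)[[1L]]
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
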