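# Independent brute-force oracles. Each recomputes its quantity with plain
# loops straight from the defining formula, sharing no scoring code with the
# package implementations it checks.

# Okapi BM25 over pre-tokenized documents: score every document.
oracle_bm25 <- function(doc_tokens, query_tokens, k1 = 1.2, b = 0.75) {
  N <- length(doc_tokens)
  lens <- vapply(doc_tokens, length, 0L)
  avgdl <- mean(lens)
  scores <- numeric(N)
  for (t in unique(query_tokens)) {
    df <- sum(vapply(doc_tokens, function(d) t %in% d, TRUE))
    if (df == 0) next
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    for (i in seq_len(N)) {
      tf <- sum(doc_tokens[[i]] == t)
      if (tf == 0) next
      scores[i] <- scores[i] +
        idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * lens[i] / avgdl))
    }
  }
  scores
}

# Score every KB document, sort, take k, count annotations: the reference
# for classify_knn.
oracle_knn <- function(kb, corpus, text, k, m = Inf, exclude = character(0),
                       allowed = NULL) {
  pmids <- intersect(names(kb$annotations), corpus$pmid)
  idx <- match(pmids, corpus$pmid)
  doc_tokens <- lapply(paste(corpus$title[idx], corpus$text[idx]), tokenize)
  q <- tokenize(text)
  scores <- oracle_bm25(doc_tokens, q)
  keep <- scores > 0 & !pmids %in% exclude
  pm <- pmids[keep]; sc <- scores[keep]
  ord <- order(-sc, pm)
  pm <- pm[ord][seq_len(min(k, length(pm)))]
  sc <- sc[ord][seq_len(min(k, length(pm)))]
  tally <- list()
  for (i in seq_along(pm)) {
    for (g in kb$annotations[[pm[i]]]) {
      if (is.null(tally[[g]])) tally[[g]] <- c(0, 0)
      tally[[g]] <- tally[[g]] + c(1, sc[i])
    }
  }
  if (!length(tally)) {
    return(data.frame(go_id = character(0), score = numeric(0)))
  }
  out <- data.frame(go_id = names(tally),
                    score = vapply(tally, `[`, 0, 1),
                    sim = vapply(tally, `[`, 0, 2),
                    stringsAsFactors = FALSE)
  if (!is.null(allowed)) out <- out[out$go_id %in% allowed, , drop = FALSE]
  out <- out[order(-out$score, -out$sim, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, m)
}

# Precision at every rank, take the max.
oracle_top_precision <- function(ranked, gold) {
  best <- 0
  hits <- 0
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% gold) hits <- hits + 1
    best <- max(best, hits / i)
  }
  best
}

oracle_recall_at <- function(ranked, gold, r) {
  found <- 0
  for (g in gold) {
    if (g %in% ranked[seq_len(min(r, length(ranked)))]) found <- found + 1
  }
  found / length(gold)
}

# Exhaustive sign-flip enumeration via expand.grid (independent of the
# bit-twiddling in the package's exact mode).
oracle_signflip_p <- function(d) {
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
  obs <- abs(mean(d))
  mean(abs(grid %*% d) / length(d) >= obs - 1e-12)
}
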