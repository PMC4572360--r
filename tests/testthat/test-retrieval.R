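test_that("tokenize normalizes, drops stopwords and keeps slashes", {
  expect_equal(tokenize("Catalytic activity of the enzyme"),
               c("catalytic", "activity", "enzyme"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("serine/threonine kinase"),
               c("serine/threonine", "kinase"))
  expect_equal(tokenize("THE OF AND"), character(0))
  expect_equal(tokenize("The Enzyme!", stopwords = character(0)),
               c("the", "enzyme"))
  expect_equal(s_stem(c("kinases", "activities", "bodies", "pass", "virus")),
               c("kinase", "activity", "body", "pass", "virus"))
})

test_that("build_index records postings, lengths and averages", {
  corpus <- make_tiny_corpus(c("catalytic activity of the enzyme",
                               "enzyme binding",
                               "protein binding activity"))
  idx <- build_index(corpus)
  expect_equal(idx$n_docs, 3L)
  expect_equal(unname(idx$doc_lengths), c(3L, 2L, 3L))
  expect_equal(idx$avg_doc_length, 8 / 3)
  expect_equal(idx$postings_doc[["catalytic"]], 1L)  # single-doc token
  expect_identical(build_index(corpus), idx)          # deterministic rebuild
  expect_error(build_index(corpus[0, ]), "empty corpus")
})

test_that("BM25 matches the hand-computed three-document example", {
  # tokens: d1 = {catalytic, activity, enzyme}, d2 = {enzyme, binding},
  # d3 = {protein, binding, activity}; query = {catalytic, activity};
  # N = 3, avgdl = 8/3, k1 = 1.2, b = 0.75.
  # idf(catalytic) = ln(1 + 2.5/1.5), idf(activity) = ln(1 + 1.5/2.5);
  # for tf = 1 and len = 3 the tf part is 2.2 / (1 + 1.2*(0.25 + 0.75*9/8)).
  corpus <- make_tiny_corpus(c("catalytic activity of the enzyme",
                               "enzyme binding",
                               "protein binding activity"))
  idx <- build_index(corpus)
  res <- search_index(idx, "catalytic activity")
  tfpart <- 2.2 / (1 + 1.2 * (0.25 + 0.75 * (3 / (8 / 3))))
  exp_d1 <- (log(1 + 2.5 / 1.5) + log(1 + 1.5 / 2.5)) * tfpart
  exp_d3 <- log(1 + 1.5 / 2.5) * tfpart
  expect_equal(res$pmid, c("1", "3"))
  expect_equal(res$score[1], exp_d1, tolerance = 1e-9)
  expect_equal(res$score[2], exp_d3, tolerance = 1e-9)
  # query token absent everywhere -> empty result
  expect_equal(nrow(search_index(idx, "ribosome")), 0L)
  expect_error(search_index(idx, "of the"), "empty after tokenization")
})

test_that("search agrees with the score-every-document oracle", {
  for (seed in c(1, 2, 3)) {
    vocab <- paste0("w", 1:40)
    texts <- with_seed(seed, vapply(1:120, function(i) {
      paste(sample(vocab, sample(5:30, 1), replace = TRUE), collapse = " ")
    }, ""))
    corpus <- make_tiny_corpus(texts, pmids = sprintf("d%03d", 1:120))
    idx <- build_index(corpus)
    query <- with_seed(seed + 100, paste(sample(vocab, 4), collapse = " "))
    got <- search_index(idx, query, retrieval_params(n_retrieved = 120))
    want <- oracle_bm25(lapply(texts, tokenize), tokenize(query))
    keep <- want > 0
    ord <- order(-want[keep], corpus$pmid[keep])
    expect_equal(got$pmid, corpus$pmid[keep][ord])
    expect_equal(got$score, want[keep][ord], tolerance = 1e-12)
  }
})

test_that("BM25 score is monotone in term frequency at fixed length", {
  corpus <- make_tiny_corpus(c("apple pear pear plum",
                               "apple apple pear plum",
                               "apple apple apple plum"))
  res <- search_index(build_index(corpus), "apple")
  expect_equal(res$pmid, c("3", "2", "1"))
  expect_true(all(diff(res$score) < 0))
})

test_that("adding an unrelated average-length document rescales but does not reorder", {
  # the new document has the average length, so only idf changes
  base <- c("kinase signal pathway", "kinase kinase signal",
            "other stuff entirely")
  r1 <- search_index(build_index(make_tiny_corpus(base)), "kinase")
  r2 <- search_index(build_index(make_tiny_corpus(c(base, "unrelated text here"),
                                                  pmids = c("1", "2", "3", "4"))),
                     "kinase")
  expect_equal(r1$pmid, r2$pmid)
  # single-token query: only the shared idf factor changes
  expect_equal(r1$score[1] / r1$score[2], r2$score[1] / r2$score[2],
               tolerance = 1e-12)
})

test_that("ties break by ascending pmid and n_retrieved caps the output", {
  corpus <- make_tiny_corpus(rep("same text", 4), pmids = c("9", "2", "7", "1"))
  res <- search_index(build_index(corpus), "same")
  expect_equal(res$pmid, c("1", "2", "7", "9"))
  res2 <- search_index(build_index(corpus), "same",
                       retrieval_params(n_retrieved = 2))
  expect_equal(res2$pmid, c("1", "2"))
})

test_that("boolean_recency requires all tokens and orders by date", {
  corpus <- make_tiny_corpus(
    c("alpha beta", "alpha beta gamma", "alpha only here", "beta alpha"),
    pmids = c("1", "2", "3", "4"),
    dates = c("2005-01-01", "2011-07-01", "2014-01-01", "2011-07-01"))
  idx <- build_index(corpus)
  res <- search_index(idx, "alpha beta",
                      retrieval_params(mode = "boolean_recency"))
  # doc 3 lacks "beta"; 2 and 4 tie on date and order by pmid
  expect_equal(res$pmid, c("2", "4", "1"))
  expect_equal(nrow(search_index(idx, "alpha gamma delta",
                                 retrieval_params(mode = "boolean_recency"))), 0L)
  undated <- build_index(make_tiny_corpus("alpha beta"))
  expect_error(search_index(undated, "alpha",
                            retrieval_params(mode = "boolean_recency")),
               "requires document dates")
})
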