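test_that("top_precision is the best precision over all ranks", {
  expect_equal(top_precision(c("a", "b", "c"), "a"), 1.0)
  # pattern miss, hit, hit, miss: max(0, 1/2, 2/3, 2/4) = 2/3
  expect_equal(top_precision(c("x", "a", "b", "y"), c("a", "b", "z")), 2 / 3)
  expect_equal(top_precision(c("x", "y"), "a"), 0)
  expect_equal(top_precision(character(0), "a"), 0)
  expect_error(top_precision(c("a", "a"), "a"), "duplicate")
})

test_that("recall_at counts gold found in the top r", {
  expect_equal(recall_at(c("a", "b", "x", "y", "z"), c("a", "b", "c"), 5), 2 / 3)
  expect_equal(recall_at(c("a", "b"), c("a", "b"), 2), 1.0)
  expect_equal(recall_at(character(0), c("a"), 5), 0)
  expect_error(recall_at(c("a"), character(0), 5), "empty")
  # monotone non-decreasing in r; never exceeds top_precision's best rank
  ranked <- paste0("t", 1:20)
  gold <- c("t3", "t9", "t15")
  rs <- vapply(1:20, function(r) recall_at(ranked, gold, r), 0)
  expect_true(all(diff(rs) >= 0))
})

test_that("metric implementations match brute-force enumeration", {
  universe <- sprintf("GO:%07d", 1:40)
  for (i in 1:50) {
    inst <- with_seed(1000 + i, list(
      ranked = sample(universe, sample(0:25, 1)),
      gold = sample(universe, sample(1:6, 1)),
      r = sample(1:10, 1)))
    expect_equal(top_precision(inst$ranked, inst$gold),
                 oracle_top_precision(inst$ranked, inst$gold))
    expect_equal(recall_at(inst$ranked, inst$gold, inst$r),
                 oracle_recall_at(inst$ranked, inst$gold, inst$r))
  }
})

test_that("evaluate_answers macro-averages with strict id matching", {
  ont <- tiny_ontology()
  bm <- goqa:::new_benchmark(
    question = c("q1", "q2"), entity = c("x", "y"),
    namespace = c("molecular_function", "molecular_function"),
    gold = list("GO:0000003", "GO:0000002"))
  mk_answers <- function(ids, q) {
    a <- macro_read(stats::setNames(as.list(ids), paste0("p", seq_along(ids))),
                    "molecular_function", ont)
    attr(a, "question") <- structure(list(raw = q), class = "goqa_question")
    a
  }
  # q1 answered at rank 1; q2 missed entirely
  rep <- evaluate_answers(bm, list(mk_answers("GO:0000003", "q1"),
                                   mk_answers("GO:0000001", "q2")),
                          r = 5, ont)
  expect_equal(rep$per_question$p0, c(1, 0))
  expect_equal(rep$macro_p0, 0.5)
  # an alt id of a gold term counts after resolution
  rep2 <- evaluate_answers(bm[1, ], list(mk_answers("GO:1111111", "q1")), 5, ont)
  expect_equal(rep2$macro_p0, 0)  # GO:1111111 resolves to GO:0000002, not gold
  bm2 <- bm; bm2$gold <- list("GO:0000002", "GO:0000002")
  rep3 <- evaluate_answers(bm2[1, ], list(mk_answers("GO:1111111", "q1")), 5, ont)
  expect_equal(rep3$macro_p0, 1)
  # a gold term's child is strictly wrong (no hierarchical credit)
  repc <- evaluate_answers(bm[2, ], list(mk_answers("GO:0000003", "q2")), 5, ont)
  expect_equal(repc$macro_p0, 0)
  # missing answers score zero, and mismatched questions are an error
  repm <- evaluate_answers(bm, list(mk_answers("GO:0000003", "q1"), NULL), 5, ont)
  expect_equal(repm$per_question$recall, c(1, 0))
  expect_error(evaluate_answers(bm, list(mk_answers("GO:0000003", "q2"),
                                         mk_answers("GO:0000002", "q2")),
                                5, ont),
               "but the benchmark entry")
})

test_that("the sign-flip randomization test behaves as a paired test", {
  a <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(paired_randomization_test(a, a, 200, seed = 1), 1.0)
  p1 <- paired_randomization_test(a, rev(a), 500, seed = 7)
  expect_equal(p1, paired_randomization_test(a, rev(a), 500, seed = 7))
  expect_error(paired_randomization_test(a, a[-1]), "differ in length")
})

test_that("exact enumeration matches the independent oracle and bounds sampling", {
  for (seed in c(3, 4)) {
    d <- with_seed(seed, round(stats::runif(8, -1, 1), 2))
    a <- d; b <- rep(0, 8)
    p_exact <- paired_randomization_test(a, b, exact = TRUE)
    expect_equal(p_exact, oracle_signflip_p(d))
    # sampled estimate converges on the exact value
    p_samp <- paired_randomization_test(a, b, 20000, seed = 99)
    se <- sqrt(p_exact * (1 - p_exact) / 20000)
    expect_lt(abs(p_samp - p_exact), 4 * se + 2e-4)
  }
})

test_that("published ARVCF example scores reproduce from the printed table", {
  ans <- utils::read.delim(system.file("extdata", "arvcf_answers.tsv",
                                       package = "goqa"))
  gold <- utils::read.delim(system.file("extdata", "arvcf_gold.tsv",
                                        package = "goqa"))$go_id
  ranked <- function(sys) ans$go_id[ans$system == sys][order(ans$rank[ans$system == sys])]
  # the supervised pipeline returned all 3 gold terms at ranks 1-3
  expect_equal(top_precision(ranked("GOCat"), gold), 1.0)
  expect_equal(recall_at(ranked("GOCat"), gold, 5), 1.0)
  # both dictionary pipelines peak at half precision or less
  expect_equal(top_precision(ranked("EAGL"), gold), 0.25)
  expect_equal(top_precision(ranked("GoPubMed"), gold), 0.5)
})

test_that("published nitriles example precision follows the printed flags", {
  ans <- utils::read.delim(system.file("extdata", "nitriles_answers.tsv",
                                       package = "goqa"))
  p0_of <- function(sys) {
    sub <- ans[ans$system == sys, ]
    sub <- sub[order(sub$rank), ]
    top_precision(sub$go_id, sub$go_id[sub$correct == 1])
  }
  expect_equal(p0_of("EAGL"), 0.5)     # first hit at rank 3, second at 4
  expect_equal(p0_of("GOCat"), 1.0)    # hit at rank 1
  expect_equal(p0_of("GoPubMed"), 1.0) # hit at rank 1
})
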