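test_that("read_documents parses well-formed corpora and flags bad rows", {
  lines <- c("pmid\ttitle\ttext\tdate",
             "1\tt one\tsome text here\t2010-01-01",
             "2\tt two\tmore text\t",
             "3\tt three\tagain text\t2012-06-30")
  corpus <- read_documents(lines)
  expect_s3_class(corpus, "goqa_corpus")
  expect_equal(nrow(corpus), 3L)
  expect_true(is.na(corpus$date[2]))

  dup <- c("pmid\ttitle\ttext", "1\ta\told text", "1\ta\tnew text")
  expect_warning(cd <- read_documents(dup), "duplicate pmid")
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$text, "new text")

  bad <- c("pmid\ttitle\ttext", "1\ta\tok", "2\tb\t")
  expect_error(read_documents(bad), "line 3.*missing text")
})

test_that("document writer round-trips through the reader", {
  w <- explicit_micro_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_documents(w$corpus, path)
  back <- read_documents(path)
  expect_equal(back$pmid, w$corpus$pmid)
  expect_equal(back$text, w$corpus$text)
  expect_equal(back$date, w$corpus$date)
})

test_that("read_gaf filters evidence, qualifiers and references", {
  ont <- tiny_ontology()
  rows <- c("!gaf-version: 2.1",
            gaf_line("10", "GO:0000002", "IDA"),
            gaf_line("10", "GO:0000003", "IEA"),
            gaf_line("11", "GO:0000003", "IEA"),
            gaf_line("11", "GO:0000002", "EXP"),
            gaf_line("12", "GO:0000003", "TAS"))
  kb <- read_gaf(rows, ont)  # default: everything except IEA
  expect_equal(nrow(kb$provenance), 3L)
  expect_equal(sort(names(kb$annotations)), c("10", "11", "12"))

  kb_ida <- read_gaf(rows, ont, evidence_filter = "IDA")
  expect_equal(nrow(kb_ida$provenance), 1L)

  not_row <- c(gaf_line("10", "GO:0000002", "IDA", qualifier = "NOT|enables"),
               gaf_line("10", "GO:0000003", "IDA"))
  kb_not <- read_gaf(not_row, ont)
  expect_equal(kb_not$annotations[["10"]], "GO:0000003")

  # same (pmid, GO id) under two evidence codes collapses to one entry
  dup <- c(gaf_line("10", "GO:0000002", "IDA"),
           gaf_line("10", "GO:0000002", "TAS"))
  expect_equal(nrow(read_gaf(dup, ont)$provenance), 1L)

  # non-literature rows are dropped; alt ids resolve; junk ids are skipped
  misc <- c(gaf_line("13", "GO:0000002", "IDA", ref = "GO_REF:0000033"),
            gaf_line("14", "GO:1111111", "IDA"))
  expect_warning(kb2 <- read_gaf(c(misc, gaf_line("15", "XX:0000001", "IDA")), ont),
                 "non-GO")
  expect_equal(names(kb2$annotations), "14")
  expect_equal(kb2$annotations[["14"]], "GO:0000002")
})

test_that("write_gaf round-trips the knowledge base", {
  w <- explicit_micro_world()
  path <- withr::local_tempfile(fileext = ".gaf")
  write_gaf(w$kb, path, w$ontology)
  back <- read_gaf(path, w$ontology)
  expect_equal(back$annotations, w$kb$annotations)
})

test_that("hold_out removes pmids without touching the input", {
  w <- explicit_micro_world()
  all_pm <- names(w$kb$annotations)
  kept <- hold_out(w$kb, all_pm[1:5])
  expect_equal(length(kept$annotations), length(all_pm) - 5L)
  expect_false(any(all_pm[1:5] %in% names(kept$annotations)))
  expect_equal(length(w$kb$annotations), length(all_pm))  # input unchanged
  expect_equal(hold_out(w$kb, "no-such-pmid")$annotations, w$kb$annotations)
  emptied <- hold_out(w$kb, all_pm)
  expect_length(emptied$annotations, 0L)
  expect_error(build_kb_index(emptied, w$corpus), "no knowledge-base abstract")
})

test_that("build_micro_benchmark samples reproducibly within bounds", {
  w <- explicit_micro_world()
  b1 <- build_micro_benchmark(w$kb, w$corpus, 20, seed = 9)
  b2 <- build_micro_benchmark(w$kb, w$corpus, 20, seed = 9)
  expect_equal(b1, b2)
  avail <- intersect(names(w$kb$annotations), w$corpus$pmid)
  ball <- build_micro_benchmark(w$kb, w$corpus, length(avail), seed = 1)
  expect_setequal(vapply(ball, `[[`, "", "pmid"), avail)
  expect_error(build_micro_benchmark(w$kb, w$corpus, length(avail) + 1),
               "only")
})

test_that("read_benchmark validates gold sets against the ontology", {
  ont <- tiny_ontology()
  ok <- c("question\tentity\tnamespace\tgold",
          "what molecular functions are affected by X ?\tX\tmolecular_function\tGO:0000002;GO:0000003",
          "what cellular component is the location of Y?\tY\tcellular_component\tGO:0000006")
  bm <- read_benchmark(textConnection(ok), ont)
  expect_equal(nrow(bm), 2L)
  expect_equal(bm$gold[[1]], c("GO:0000002", "GO:0000003"))

  # alt ids in the gold column resolve to primaries
  alt <- c("question\tentity\tnamespace\tgold",
           "q\tX\tmolecular_function\tGO:1111111")
  expect_equal(read_benchmark(textConnection(alt), ont)$gold[[1]], "GO:0000002")

  cross <- c("question\tentity\tnamespace\tgold",
             "q\tX\tmolecular_function\tGO:0000006")
  expect_error(read_benchmark(textConnection(cross), ont),
               "outside namespace molecular_function")

  empty <- c("question\tentity\tnamespace\tgold", "q\tX\tmolecular_function\t")
  expect_error(read_benchmark(textConnection(empty), ont), "empty gold")
})

test_that("benchmark writer round-trips through the reader", {
  w <- qa_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(w$benchmark, path)
  back <- read_benchmark(path, w$ontology)
  expect_equal(back$question, w$benchmark$question)
  expect_equal(back$gold, w$benchmark$gold)
})
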