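## Ranked-answer evaluation: top precision (P0), recall at rank, strict-id
## benchmark scoring and a paired sign-flip randomization test.
##
## Matching is strict: an answer counts only if its primary GO id equals a
## gold primary id after alt-id resolution. No hierarchical or semantic
## credit is given — a gold term's child is simply wrong.

#' Top precision (interpolated precision at recall 0)
#'
#' The best precision observed at any rank of the list:
#' \eqn{P_0 = \max_i |top_i \cap gold| / i}. 0 when no gold item appears
#' (including the empty list).
#'
#' @param ranked Character vector of GO ids, best first, no duplicates.
#' @param gold Character vector of gold ids.
#' @return Number in \[0, 1\].
#' @export
top_precision <- function(ranked, gold) {
  if (anyDuplicated(ranked)) stop("ranked list contains duplicate ids")
  if (!length(ranked)) return(0)
  rel <- ranked %in% gold
  if (!any(rel)) return(0)
  max(cumsum(rel) / seq_along(rel))
}

#' Recall at rank r
#'
#' Fraction of the gold ids found in the top `r` of the ranked list.
#'
#' @param ranked Character vector of GO ids, best first.
#' @param gold Non-empty character vector of gold ids.
#' @param r Rank cutoff (>= 1).
#' @return Number in \[0, 1\].
#' @export
recall_at <- function(ranked, gold, r) {
  if (!length(gold)) stop("gold set is empty")
  stopifnot(r >= 1)
  mean(gold %in% utils::head(ranked, r))
}

#' Evaluate answer sets against a question benchmark
#'
#' One answer set per benchmark entry (a `NULL` or missing set scores 0, so
#' macro averages stay comparable across systems). Ids on both sides are
#' resolved through the ontology's alt-id map; matching is then strict id
#' equality. Macro metrics are unweighted means over questions.
#'
#' @param benchmark A `goqa_benchmark`.
#' @param answer_sets List of `goqa_answerset` (or `NULL`s), parallel to the
#'   benchmark rows; an attached question must match the benchmark entry.
#' @param r Rank cutoff for recall.
#' @param ontology A `goqa_ontology`.
#' @return A `goqa_eval_report`: list with `per_question` (data.frame
#'   question, p0, recall), `macro_p0`, `macro_recall`, `r`.
#' @export
evaluate_answers <- function(benchmark, answer_sets, r, ontology) {
  n <- nrow(benchmark)
  if (length(answer_sets) != n) {
    stop("expected ", n, " answer sets, got ", length(answer_sets))
  }
  p0 <- numeric(n); rec <- numeric(n)
  for (i in seq_len(n)) {
    as_i <- answer_sets[[i]]
    gold <- resolve_id(ontology, benchmark$gold[[i]])
    if (is.null(as_i)) {
      p0[i] <- 0; rec[i] <- 0
      next
    }
    q <- attr(as_i, "question")
    if (!is.null(q) && !identical(q$raw, benchmark$question[i])) {
      stop("answer set ", i, " is for question '", q$raw,
           "' but the benchmark entry is '", benchmark$question[i], "'")
    }
    ranked <- resolve_id(ontology, as_i$answers$go_id)
    p0[i] <- top_precision(ranked, gold)
    rec[i] <- recall_at(ranked, gold, r)
  }
  structure(
    list(per_question = data.frame(question = benchmark$question, p0 = p0,
                                   recall = rec, stringsAsFactors = FALSE),
         macro_p0 = mean(p0), macro_recall = mean(rec), r = r),
    class = "goqa_eval_report"
  )
}

#' @export
print.goqa_eval_report <- function(x, ...) {
  cat("<goqa_eval_report> ", nrow(x$per_question), " questions\n",
      sprintf("  macro P0:        %.3f\n", x$macro_p0),
      sprintf("  macro recall@%-3d %.3f\n", x$r, x$macro_recall), sep = "")
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param report A `goqa_eval_report`.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_eval_report <- function(report, file) {
  pq <- report$per_question
  lines <- c(
    sprintf("question\tp0\trecall_at_%d", report$r),
    sprintf("%s\t%.6g\t%.6g", pq$question, pq$p0, pq$recall),
    sprintf("MACRO\t%.6g\t%.6g", report$macro_p0, report$macro_recall)
  )
  writeLines(lines, file)
  invisible(file)
}

#' Micro-reading evaluation of a classifier
#'
#' Classifies each benchmark abstract on its own and scores the ranked
#' prediction list against the abstract's curated gold terms. For
#' knowledge-base classifiers the abstract's own pmid is excluded from the
#' neighbour pool (leave-out).
#'
#' @param micro_benchmark A `goqa_micro_benchmark` from
#'   [build_micro_benchmark()].
#' @param classifier Any classifier accepted by [classify_document()].
#' @param ontology A `goqa_ontology`.
#' @param m Prediction-list size per abstract.
#' @param r Rank cutoff for recall.
#' @param allowed_namespaces Optional namespaces restricting candidates.
#' @param exclude_self Exclude each abstract's pmid from the knowledge base?
#' @return A `goqa_micro_report`: list with `per_doc` (pmid, p0, recall),
#'   `term_hits` (pmid, go_id, hit — one row per gold term, for stratified
#'   analyses), `macro_p0`, `macro_recall`, `r`.
#' @export
evaluate_micro <- function(micro_benchmark, classifier, ontology, m = 5L,
                           r = 5L, allowed_namespaces = NULL,
                           exclude_self = TRUE) {
  allowed <- if (is.null(allowed_namespaces)) NULL else
    unlist(lapply(allowed_namespaces, function(ns) namespace_terms(ontology, ns)))
  n <- length(micro_benchmark)
  p0 <- numeric(n); rec <- numeric(n)
  th_pmid <- character(0); th_go <- character(0); th_hit <- logical(0)
  for (i in seq_len(n)) {
    e <- micro_benchmark[[i]]
    gold <- resolve_id(ontology, e$gold)
    pred <- tryCatch(
      classify_document(classifier, paste(e$title, e$text), m = max(m, r),
                        allowed_ids = allowed,
                        exclude_pmids = if (exclude_self) e$pmid else NULL),
      error = function(err) NULL
    )
    ranked <- if (is.null(pred)) character(0) else
      resolve_id(ontology, pred$go_id)
    p0[i] <- top_precision(ranked, gold)
    rec[i] <- recall_at(ranked, gold, r)
    th_pmid <- c(th_pmid, rep(e$pmid, length(gold)))
    th_go <- c(th_go, gold)
    th_hit <- c(th_hit, gold %in% utils::head(ranked, r))
  }
  structure(
    list(per_doc = data.frame(
           pmid = vapply(micro_benchmark, `[[`, "", "pmid"),
           p0 = p0, recall = rec, stringsAsFactors = FALSE),
         term_hits = data.frame(pmid = th_pmid, go_id = th_go, hit = th_hit,
                                stringsAsFactors = FALSE),
         macro_p0 = mean(p0), macro_recall = mean(rec), r = r),
    class = "goqa_micro_report"
  )
}

#' @export
print.goqa_micro_report <- function(x, ...) {
  cat("<goqa_micro_report> ", nrow(x$per_doc), " abstracts\n",
      sprintf("  macro P0:        %.3f\n", x$macro_p0),
      sprintf("  macro recall@%-3d %.3f\n", x$r, x$macro_recall), sep = "")
  invisible(x)
}

#' Gold-term recall stratified by knowledge-base support
#'
#' Supervised classifiers can only learn terms that curation has already
#' assigned often enough; roughly ten training instances per class is the
#' usual rule of thumb. This splits the per-term recall of a micro report by
#' each term's number of knowledge-base assignments.
#'
#' @param micro_report A `goqa_micro_report`.
#' @param kb The `goqa_kb` the classifier was trained on.
#' @param threshold Support cutoff (default 10 assignments).
#' @return List with `recall_high`, `recall_low`, `n_high`, `n_low`,
#'   `threshold`; recall values are `NaN` when a stratum is empty.
#' @export
recall_by_support <- function(micro_report, kb, threshold = 10L) {
  support <- table(kb$provenance$go_id)
  th <- micro_report$term_hits
  s <- as.integer(support[th$go_id])
  s[is.na(s)] <- 0L
  high <- s >= threshold
  list(recall_high = mean(th$hit[high]), recall_low = mean(th$hit[!high]),
       n_high = sum(high), n_low = sum(!high), threshold = threshold)
}

#' Paired sign-flip randomization test
#'
#' Two-sided test for a difference in paired per-question scores (the
#' standard significance test for query-level IR metrics). The observed
#' statistic is `|mean(a - b)|`; under the null the sign of each paired
#' difference is exchangeable. With `exact = TRUE` all `2^n` sign
#' assignments are enumerated (n <= 20) and the p-value is the exact
#' proportion at least as extreme; otherwise `n_permutations` random sign
#' vectors are drawn and `p = (1 + #extreme) / (1 + n_permutations)`.
#'
#' @param scores_a,scores_b Equal-length numeric vectors, paired by
#'   question.
#' @param n_permutations Number of sampled sign vectors (>= 1).
#' @param seed Integer seed for the sampled mode (caller RNG untouched).
#' @param exact Enumerate all sign flips instead of sampling?
#' @return p-value in (0, 1].
#' @export
paired_randomization_test <- function(scores_a, scores_b,
                                      n_permutations = 10000L, seed = NULL,
                                      exact = FALSE) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors differ in length")
  }
  stopifnot(n_permutations >= 1)
  d <- as.numeric(scores_a) - as.numeric(scores_b)
  n <- length(d)
  obs <- abs(mean(d))
  eps <- 1e-12
  if (exact) {
    if (n > 20L) stop("exact enumeration limited to 20 pairs")
    total <- 2^n
    hits <- 0L
    bits <- bitwShiftL(1L, 0:(n - 1L))
    for (mask in 0:(total - 1L)) {
      signs <- ifelse(bitwAnd(mask, bits) > 0L, -1, 1)
      if (abs(mean(signs * d)) >= obs - eps) hits <- hits + 1L
    }
    return(hits / total)
  }
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE), nrow = n)
    perm <- abs(colMeans(signs * d))
    (1 + sum(perm >= obs - eps)) / (1 + n_permutations)
  })
}
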