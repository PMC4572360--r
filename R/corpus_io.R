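## Corpus, GAF knowledge base and question-benchmark IO.
##
## Documents are abstracts keyed by PMID; the knowledge base maps PMIDs to
## curated GO ids and is the k-NN classifier's training data; benchmarks pair
## questions with gold GO ids for macro-reading evaluation.

#' Read a document corpus (TSV)
#'
#' Tab-separated with a header; required columns `pmid`, `title`, `text`,
#' optional `date` (ISO). On duplicate PMIDs the last record wins with a
#' warning; malformed rows (extra fields, empty pmid or text) raise an error
#' naming the line.
#'
#' @param file Path or connection.
#' @return A `goqa_corpus` data.frame with columns pmid, title, text, date.
#' @export
read_documents <- function(file) {
  lines <- input_lines(file)
  if (length(lines) < 1L) stop("empty document file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  req <- c("pmid", "title", "text")
  if (!all(req %in% header)) {
    stop("document file header must contain: ", paste(req, collapse = ", "))
  }
  nc <- length(header)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    f <- fields[[i + 1L]]
    if (length(f) > nc) stop("malformed record on line ", i + 1L, ": too many fields")
    f <- c(f, rep("", nc - length(f)))
    names(f) <- header
    if (!nzchar(f[["pmid"]])) stop("malformed record on line ", i + 1L, ": empty pmid")
    if (!nzchar(f[["text"]])) stop("malformed record on line ", i + 1L, ": missing text field")
    rows[[i]] <- f
  }
  if (!length(rows)) stop("document file has a header but no records")
  mat <- do.call(rbind, rows)
  corpus <- data.frame(
    pmid = mat[, "pmid"], title = mat[, "title"], text = mat[, "text"],
    stringsAsFactors = FALSE
  )
  corpus$date <- if ("date" %in% header) {
    as.Date(ifelse(nzchar(mat[, "date"]), mat[, "date"], NA))
  } else {
    as.Date(rep(NA, nrow(corpus)))
  }
  dup <- duplicated(corpus$pmid, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate pmid(s) ", paste(unique(corpus$pmid[dup]), collapse = ", "),
            "; keeping the last record of each")
    corpus <- corpus[!dup, , drop = FALSE]
    rownames(corpus) <- NULL
  }
  as_corpus(corpus)
}

#' Build a corpus object from a data.frame
#'
#' @param df Data.frame with columns pmid, title, text and optionally date.
#' @return A `goqa_corpus`.
#' @export
as_corpus <- function(df) {
  stopifnot(all(c("pmid", "title", "text") %in% names(df)))
  if (anyDuplicated(df$pmid)) stop("duplicate pmids in corpus")
  if (!"date" %in% names(df)) df$date <- as.Date(rep(NA, nrow(df)))
  df$pmid <- as.character(df$pmid)
  rownames(df) <- NULL
  class(df) <- c("goqa_corpus", "data.frame")
  df
}

#' Write a document corpus (TSV)
#'
#' Tabs and newlines inside fields are replaced by spaces so the file stays
#' one record per line.
#'
#' @param corpus A `goqa_corpus`.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_documents <- function(corpus, file) {
  clean <- function(x) gsub("[\t\r\n]+", " ", x)
  lines <- c(
    "pmid\ttitle\ttext\tdate",
    sprintf("%s\t%s\t%s\t%s", clean(corpus$pmid), clean(corpus$title),
            clean(corpus$text),
            ifelse(is.na(corpus$date), "", as.character(corpus$date)))
  )
  writeLines(lines, file)
  invisible(file)
}

#' Read a GAF 2.x annotation file into a knowledge base
#'
#' Keeps rows whose reference column carries a `PMID:` entry (the knowledge
#' base is literature-keyed), whose qualifier does not contain `NOT`
#' (negative assertions are not answers), and whose evidence code passes the
#' filter. GO ids are resolved through the ontology's alt-id map; rows with
#' malformed or unresolvable ids are skipped with a warning.
#'
#' @param file Path or connection.
#' @param ontology A `goqa_ontology` used to resolve ids.
#' @param evidence_filter Character vector of evidence codes to keep, or
#'   `NULL` (default) for "everything except IEA", i.e. manually curated
#'   annotations only.
#' @return A `goqa_kb`: list with `annotations` (named list pmid ->
#'   sorted unique GO ids) and `provenance` (data.frame pmid, go_id, evidence).
#' @export
read_gaf <- function(file, ontology, evidence_filter = NULL) {
  lines <- input_lines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  pm <- character(0); go <- character(0); ev <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 7L) {
      warning("GAF row ", i, ": fewer than 7 columns, skipped")
      next
    }
    if (grepl("\\bNOT\\b", f[[4L]])) next
    goid <- f[[5L]]
    if (!grepl(GO_ID_RE, goid)) {
      warning("GAF row ", i, ": non-GO ontology id '", goid, "', skipped")
      next
    }
    code <- f[[7L]]
    if (is.null(evidence_filter)) {
      if (identical(code, "IEA")) next
    } else if (!code %in% evidence_filter) {
      next
    }
    refs <- strsplit(f[[6L]], "|", fixed = TRUE)[[1L]]
    pmids <- sub("^PMID:", "", refs[startsWith(refs, "PMID:")])
    if (!length(pmids)) next
    resolved <- tryCatch(resolve_id(ontology, goid), error = function(e) NA_character_)
    if (is.na(resolved)) {
      warning("GAF row ", i, ": GO id ", goid, " not in ontology, skipped")
      next
    }
    pm <- c(pm, pmids)
    go <- c(go, rep(resolved, length(pmids)))
    ev <- c(ev, rep(code, length(pmids)))
  }
  new_kb(pm, go, ev)
}

new_kb <- function(pmid, go_id, evidence) {
  prov <- data.frame(pmid = pmid, go_id = go_id, evidence = evidence,
                     stringsAsFactors = FALSE)
  prov <- prov[!duplicated(prov[c("pmid", "go_id")]), , drop = FALSE]
  prov <- prov[order(prov$pmid, prov$go_id), , drop = FALSE]
  rownames(prov) <- NULL
  ann <- lapply(split(prov$go_id, prov$pmid), function(g) sort(unique(g)))
  structure(list(annotations = ann, provenance = prov), class = "goqa_kb")
}

#' @export
print.goqa_kb <- function(x, ...) {
  cat("<goqa_kb> ", length(x$annotations), " abstracts, ",
      nrow(x$provenance), " annotations, ",
      length(unique(x$provenance$go_id)), " distinct GO terms\n", sep = "")
  invisible(x)
}

#' Write a knowledge base as GAF 2.1
#'
#' @param kb A `goqa_kb`.
#' @param file Path or connection.
#' @param ontology A `goqa_ontology` (supplies the aspect column F/C/P).
#' @return `file`, invisibly.
#' @export
write_gaf <- function(kb, file, ontology) {
  aspect <- c(molecular_function = "F", cellular_component = "C",
              biological_process = "P")
  p <- kb$provenance
  asp <- vapply(p$go_id, function(g) aspect[[ontology$terms[[g]]$namespace]], "")
  rows <- sprintf(
    "GOQA\tOBJ:%s\t-\t\t%s\tPMID:%s\t%s\t\t%s\t\t\tprotein\ttaxon:0000\t20120801\tGOQA\t\t",
    p$pmid, p$go_id, p$pmid, p$evidence, asp
  )
  writeLines(c("!gaf-version: 2.1", rows), file)
  invisible(file)
}

#' Remove abstracts from a knowledge base
#'
#' The leave-out protocol for fair evaluation: any PMID about to be
#' classified is removed from the k-NN classifier's knowledge base so a
#' document can never vote for its own curated annotations. Absent pmids are
#' ignored; the input is not modified.
#'
#' @param kb A `goqa_kb`.
#' @param pmids Character vector of pmids to drop.
#' @return A new `goqa_kb`.
#' @export
hold_out <- function(kb, pmids) {
  keep <- !kb$provenance$pmid %in% as.character(pmids)
  new_kb(kb$provenance$pmid[keep], kb$provenance$go_id[keep],
         kb$provenance$evidence[keep])
}

#' Sample a micro-reading benchmark
#'
#' Draws `n` PMIDs uniformly without replacement from those present in both
#' the knowledge base and the corpus; each entry pairs a document with its
#' curated gold GO ids.
#'
#' @param kb A `goqa_kb`.
#' @param corpus A `goqa_corpus`.
#' @param n Sample size; must not exceed the available intersection.
#' @param seed Integer seed (reproducible draw; caller RNG untouched).
#' @return A `goqa_micro_benchmark`: list of entries
#'   `list(pmid, title, text, gold)`.
#' @export
build_micro_benchmark <- function(kb, corpus, n, seed = 1L) {
  avail <- sort(intersect(names(kb$annotations), corpus$pmid))
  if (n > length(avail)) {
    stop("requested ", n, " abstracts but only ", length(avail),
         " are in both the knowledge base and the corpus")
  }
  sel <- with_seed(seed, sample(avail, n))
  idx <- match(sel, corpus$pmid)
  entries <- Map(function(p, i) {
    list(pmid = p, title = corpus$title[[i]], text = corpus$text[[i]],
         gold = kb$annotations[[p]])
  }, sel, idx)
  structure(unname(entries), class = "goqa_micro_benchmark")
}

#' Read a question benchmark (TSV)
#'
#' Columns: `question`, `entity`, `namespace`, `gold` (semicolon-joined GO
#' ids). Every gold id must resolve in the ontology and belong to the entry's
#' target namespace; violations raise an error naming the entry.
#'
#' @param file Path or connection.
#' @param ontology A `goqa_ontology`.
#' @return A `goqa_benchmark` data.frame with a list column `gold`.
#' @export
read_benchmark <- function(file, ontology) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("question", "entity", "namespace", "gold")
  if (!all(req %in% names(df))) {
    stop("benchmark header must contain: ", paste(req, collapse = ", "))
  }
  gold <- strsplit(df$gold, ";", fixed = TRUE)
  gold <- lapply(gold, function(g) trimws(g[nzchar(trimws(g))]))
  for (i in seq_len(nrow(df))) {
    if (!length(gold[[i]])) stop("benchmark entry ", i, " ('", df$question[i],
                                 "'): empty gold set")
    if (!df$namespace[i] %in% GO_NAMESPACES) {
      stop("benchmark entry ", i, ": unknown namespace ", df$namespace[i])
    }
    gold[[i]] <- sort(resolve_id(ontology, gold[[i]]))
    allowed <- namespace_terms(ontology, df$namespace[i])
    bad <- setdiff(gold[[i]], allowed)
    if (length(bad)) {
      stop("benchmark entry ", i, " ('", df$question[i], "'): gold id ",
           bad[1L], " is outside namespace ", df$namespace[i])
    }
  }
  new_benchmark(df$question, df$entity, df$namespace, gold)
}

new_benchmark <- function(question, entity, namespace, gold) {
  bm <- data.frame(question = question, entity = entity, namespace = namespace,
                   stringsAsFactors = FALSE)
  bm$gold <- gold
  class(bm) <- c("goqa_benchmark", "data.frame")
  bm
}

#' Write a question benchmark (TSV)
#'
#' @param benchmark A `goqa_benchmark`.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_benchmark <- function(benchmark, file) {
  lines <- c(
    "question\tentity\tnamespace\tgold",
    sprintf("%s\t%s\t%s\t%s", benchmark$question, benchmark$entity,
            benchmark$namespace,
            vapply(benchmark$gold, paste, "", collapse = ";"))
  )
  writeLines(lines, file)
  invisible(file)
}
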