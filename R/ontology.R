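## GO-style ontology: parsing, validation, writing and graph queries.
##
## The ontology is the answer space of the QA system: one namespace (axis) of
## GO is selected per question as the target set, and the dictionary
## classifier indexes every term's name and synonyms as pseudo-documents.

GO_ID_RE <- "^GO:[0-9]{7}$"
GO_NAMESPACES <- c("molecular_function", "cellular_component", "biological_process")

#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, synonym, alt_id,
#' is_obsolete), builds the is_a DAG, and validates it: identifiers must be
#' unique and well formed (`GO:` + 7 digits), every is_a target must exist,
#' every term needs a namespace shared with its parents, each namespace must
#' have exactly one root, the graph must be acyclic, and alt_ids may not
#' collide with primary ids. Obsolete terms are kept but flagged; they take
#' no part in the graph, the namespaces or the classifiers.
#'
#' @param file Path, connection, or character vector of OBO lines.
#' @return A `goqa_ontology`: list with `terms` (named list of term records),
#'   `roots` (named by namespace), `alt_map` (alt id -> primary id) and
#'   `levels` (longest-path depth from the namespace root, root = 0).
#' @seealso [write_obo()], [go_level()], [surface_forms()], [namespace_terms()]
#' @export
parse_obo <- function(file) {
  lines <- input_lines(file)
  lines <- sub("[ \t]+$", "", lines)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found; not an OBO file?")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[(starts[s] + 1L):(bounds[s + 1L] - 1L)]
    block <- block[nzchar(block)]
    m <- regmatches(block, regexec("^([a-z_]+): ?(.*)$", block))
    keys <- vapply(m, function(x) if (length(x) == 3L) x[2L] else "", "")
    vals <- vapply(m, function(x) if (length(x) == 3L) x[3L] else "", "")
    get1 <- function(k) {
      v <- vals[keys == k]
      if (length(v)) v[[1L]] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) stop("[Term] stanza without id")
    if (!grepl(GO_ID_RE, id)) stop("malformed term id: ", id)
    is_a <- trimws(sub("!.*$", "", vals[keys == "is_a"]))
    syn_raw <- vals[keys == "synonym"]
    sm <- regmatches(syn_raw, regexec("^\"(.*)\"[ ]*([A-Za-z_]*)", syn_raw))
    synonyms <- vapply(sm, function(x) x[2L], "")
    scopes <- vapply(sm, function(x) if (nzchar(x[3L])) x[3L] else "RELATED", "")
    terms[[id]] <- list(
      id = id,
      name = get1("name"),
      namespace = get1("namespace"),
      synonyms = unname(synonyms),
      synonym_scopes = unname(scopes),
      parents = unname(is_a),
      alt_ids = unname(vals[keys == "alt_id"]),
      obsolete = identical(get1("is_obsolete"), "true")
    )
  }
  new_ontology(terms)
}

#' Construct and validate an ontology from term records
#'
#' Used by [parse_obo()] and [make_ontology()]; enforces every structural
#' invariant (see [parse_obo()]).
#'
#' @param terms Named list of term records (fields `id`, `name`, `namespace`,
#'   `synonyms`, `synonym_scopes`, `parents`, `alt_ids`, `obsolete`).
#' @return A `goqa_ontology`.
#' @export
new_ontology <- function(terms) {
  ids <- names(terms)
  if (anyDuplicated(ids)) stop("duplicate term ids: ", ids[duplicated(ids)][1L])
  for (t in terms) {
    if (is.na(t$namespace) || !t$namespace %in% GO_NAMESPACES) {
      stop("term ", t$id, ": missing or unknown namespace")
    }
    if (is.na(t$name)) stop("term ", t$id, ": missing name")
    for (p in t$parents) {
      if (!p %in% ids) stop("dangling is_a target ", p, " in term ", t$id)
      if (!identical(terms[[p]]$namespace, t$namespace)) {
        stop("term ", t$id, " (", t$namespace, ") has parent ", p,
             " in namespace ", terms[[p]]$namespace)
      }
    }
  }
  live <- ids[!vapply(terms, `[[`, TRUE, "obsolete")]
  # single root per namespace
  roots <- character(0)
  for (ns in GO_NAMESPACES) {
    ns_ids <- live[vapply(terms[live], function(t) t$namespace == ns, TRUE)]
    if (!length(ns_ids)) next
    r <- ns_ids[vapply(terms[ns_ids], function(t) length(t$parents) == 0L, TRUE)]
    if (length(r) != 1L) {
      stop("namespace ", ns, " has ", length(r), " roots (exactly 1 required)")
    }
    roots[[ns]] <- r
  }
  # acyclicity + longest-path levels over the live is_a graph (Kahn order)
  indeg <- vapply(terms[live], function(t) length(t$parents), 0L)
  children <- stats::setNames(vector("list", length(live)), live)
  for (id in live) {
    for (p in terms[[id]]$parents) children[[p]] <- c(children[[p]], id)
  }
  levels <- stats::setNames(rep(0L, length(live)), live)
  queue <- live[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[id]]) {
      levels[[ch]] <- max(levels[[ch]], levels[[id]] + 1L)
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(live)) {
    bad <- live[indeg > 0L][1L]
    stop("cycle detected in is_a graph, involving edge ", bad, " -> ",
         terms[[bad]]$parents[1L])
  }
  # alt-id map
  alt_map <- character(0)
  for (t in terms) {
    for (a in t$alt_ids) {
      if (a %in% ids) stop("alt_id ", a, " collides with a primary id")
      if (a %in% names(alt_map)) stop("alt_id ", a, " registered twice")
      alt_map[[a]] <- t$id
    }
  }
  structure(
    list(terms = terms, roots = roots, alt_map = alt_map, levels = levels),
    class = "goqa_ontology"
  )
}

#' @export
print.goqa_ontology <- function(x, ...) {
  live <- sum(!vapply(x$terms, `[[`, TRUE, "obsolete"))
  cat("<goqa_ontology> ", length(x$terms), " terms (", live, " non-obsolete), ",
      length(x$roots), " namespaces, ", length(x$alt_map), " alt ids\n", sep = "")
  invisible(x)
}

#' Resolve a (possibly secondary) GO identifier to its primary id
#'
#' Strict-id evaluation against older annotation files needs merged terms'
#' secondary ids mapped onto the current primary id.
#'
#' @param ontology A `goqa_ontology`.
#' @param id Character vector of GO ids.
#' @return Character vector of primary ids.
#' @export
resolve_id <- function(ontology, id) {
  vapply(id, function(i) {
    if (i %in% names(ontology$terms)) return(i)
    if (i %in% names(ontology$alt_map)) return(unname(ontology$alt_map[[i]]))
    stop("unknown GO id: ", i)
  }, "", USE.NAMES = FALSE)
}

#' Ontology level of a term
#'
#' Number of edges on the longest is_a path from the namespace root down to
#' the term (root = 0). The longest path is used because in a DAG a term can
#' be reached by routes of different lengths; the longest-path depth is the
#' conventional "GO level" and is monotone: a child is always at least one
#' level below its deepest parent.
#'
#' @param ontology A `goqa_ontology`.
#' @param term_id Primary id of a non-obsolete term.
#' @return Non-negative integer.
#' @export
go_level <- function(ontology, term_id) {
  term <- ontology$terms[[term_id]]
  if (is.null(term)) stop("unknown term: ", term_id)
  if (term$obsolete) stop("term ", term_id, " is obsolete; no level defined")
  unname(ontology$levels[[term_id]])
}

#' Normalized surface forms of a term
#'
#' The term's name followed by its synonyms (all scopes), normalized with
#' [normalize_text()] and deduplicated, name first. These strings are what
#' the dictionary classifier indexes and literally matches.
#'
#' @param ontology A `goqa_ontology`.
#' @param term_id Primary id of a non-obsolete term.
#' @return Character vector of normalized forms.
#' @export
surface_forms <- function(ontology, term_id) {
  term <- ontology$terms[[term_id]]
  if (is.null(term)) stop("unknown term: ", term_id)
  if (term$obsolete) stop("term ", term_id, " is obsolete; no surface forms")
  unique(normalize_text(c(term$name, term$synonyms)))
}

#' All non-obsolete term ids of a namespace
#'
#' The target set of a question: the QA pipeline proposes these and only
#' these ids as answers for a question on that GO axis.
#'
#' @param ontology A `goqa_ontology`.
#' @param namespace One of `molecular_function`, `cellular_component`,
#'   `biological_process`.
#' @return Sorted character vector of term ids.
#' @export
namespace_terms <- function(ontology, namespace) {
  if (!namespace %in% GO_NAMESPACES) stop("unknown namespace: ", namespace)
  ids <- names(ontology$terms)
  keep <- vapply(ontology$terms, function(t) {
    !t$obsolete && t$namespace == namespace
  }, TRUE)
  sort(ids[keep])
}

#' Write an ontology as OBO 1.2
#'
#' Inverse of [parse_obo()]: the written file reparses to an ontology with
#' the same terms, edges, synonyms (and scopes), alt ids and obsolete flags.
#'
#' @param ontology A `goqa_ontology`.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_obo <- function(ontology, file) {
  out <- c("format-version: 1.2", "")
  for (id in sort(names(ontology$terms))) {
    t <- ontology$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
             paste0("namespace: ", t$namespace))
    for (a in t$alt_ids) out <- c(out, paste0("alt_id: ", a))
    if (length(t$synonyms)) {
      scopes <- t$synonym_scopes
      if (is.null(scopes) || length(scopes) != length(t$synonyms)) {
        scopes <- rep("RELATED", length(t$synonyms))
      }
      out <- c(out, sprintf("synonym: \"%s\" %s []", t$synonyms, scopes))
    }
    for (p in t$parents) {
      out <- c(out, sprintf("is_a: %s ! %s", p, ontology$terms[[p]]$name))
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  writeLines(out, file)
  invisible(file)
}
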