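#' Canonicalize a phenotype term identifier
#'
#' Term identifiers have the shape `"HP:NNNNNNN"` (uppercase prefix, colon,
#' seven-digit zero-padded number). Lowercase prefixes and unpadded numeric
#' parts are normalized; anything else is rejected.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of canonical identifiers.
#' @examples
#' canonical_term_id(c("hp:0000256", "HP:256"))
#' @export
canonical_term_id <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([A-Za-z]+):0*([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed term id(s): ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  vapply(m, function(p) sprintf("%s:%07d", toupper(p[2]), as.integer(p[3])),
         character(1))
}

#' Resolve term identifiers against an ontology
#'
#' Canonicalizes identifiers and maps alternate (merged) identifiers to their
#' canonical term. Unknown terms raise an error unless `strict = FALSE`, in
#' which case they come back as `NA`.
#'
#' @param ont an `ontology` object (from [parse_obo()]).
#' @param ids character vector of term identifiers.
#' @param strict error on unknown terms (default `TRUE`).
#' @return character vector of canonical, resolved identifiers.
#' @export
resolve_terms <- function(ont, ids, strict = TRUE) {
  stopifnot(inherits(ont, "ontology"))
  ids <- canonical_term_id(ids)
  alt <- ont$alt_map[ids]
  ids[!is.na(alt)] <- alt[!is.na(alt)]
  unknown <- !(ids %in% ont$terms)
  if (any(unknown)) {
    if (strict) {
      stop("unknown term(s): ", paste(unique(ids[unknown]), collapse = ", "),
           call. = FALSE)
    }
    ids[unknown] <- NA_character_
  }
  ids
}

new_ontology <- function(terms, parents, labels, alt_map) {
  terms <- sort(terms)
  parents <- parents[terms]
  children <- invert_edges(parents, terms)
  anc <- transitive_closure(parents, terms)
  desc <- transitive_closure(children, terms)
  structure(
    list(terms = terms, parents = parents, children = children,
         labels = labels[terms], alt_map = alt_map,
         anc = anc, desc = desc),
    class = "ontology"
  )
}

invert_edges <- function(parents, terms) {
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) children[[t]] <- character(0)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  lapply(children, sort)
}

# Reflexive-transitive closure along the given edge map, computed in
# topological order. Errors if the edge relation is cyclic.
transitive_closure <- function(edges, terms) {
  outdeg <- vapply(edges[terms], length, integer(1))
  # Kahn's algorithm on the "points-to" relation: closure of t is t plus the
  # union of closures of everything t points to.
  order <- character(0)
  remaining <- stats::setNames(outdeg, terms)
  ready <- names(remaining)[remaining == 0L]
  rev_edges <- invert_edges(edges, terms)
  while (length(ready) > 0) {
    order <- c(order, ready)
    next_ready <- character(0)
    for (n in ready) {
      for (dep in rev_edges[[n]]) {
        remaining[[dep]] <- remaining[[dep]] - 1L
        if (remaining[[dep]] == 0L) next_ready <- c(next_ready, dep)
      }
    }
    ready <- next_ready
  }
  if (length(order) < length(terms)) {
    stop("cycle detected among terms: ",
         paste(setdiff(terms, order), collapse = ", "), call. = FALSE)
  }
  closure <- stats::setNames(vector("list", length(terms)), terms)
  for (t in order) {
    closure[[t]] <- sort(unique(c(t, unlist(closure[edges[[t]]], use.names = FALSE))))
  }
  closure
}

#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 flat file and builds a directed acyclic graph of
#' phenotype terms connected by `is_a` edges only; all other relationship
#' types are ignored. Obsolete stanzas are dropped (their ids do not appear
#' among the terms), and `alt_id` entries are recorded so merged identifiers
#' resolve to their canonical term at every ingestion boundary.
#'
#' @param path path to an OBO file.
#' @return an object of class `"ontology"` with fields `terms` (sorted
#'   character vector), `parents`/`children` (named lists of character
#'   vectors, `is_a` edges), `labels` (named character), `alt_map` (named
#'   character mapping alternate to canonical ids), and precomputed
#'   reflexive-transitive closures.
#' @seealso [term_ancestors()], [term_descendants()], [read_annotations()]
#' @examples
#' obo <- system.file("extdata", "mini_hp.obo", package = "gorlin")
#' ont <- parse_obo(obo)
#' length(ont$terms)
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")

  terms <- character(0)
  labels <- character(0)
  alt_pairs <- list()
  parents <- list()

  in_term <- FALSE
  cur <- NULL
  start_line <- 0L

  flush_term <- function(cur, start_line) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id",
                   start_line), call. = FALSE)
    }
    cur
  }
  stash <- function(cur) {
    if (isTRUE(cur$obsolete)) return()
    id <- cur$id
    terms <<- c(terms, id)
    labels[id] <<- if (is.null(cur$name)) id else cur$name
    parents[[id]] <<- unique(cur$is_a)
    for (a in cur$alt_id) alt_pairs[[a]] <<- id
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s*!.*$", "", lines[i])  # strip trailing OBO comments
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      if (in_term) stash(flush_term(cur, start_line))
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list(is_a = character(0), alt_id = character(0)) else NULL
      start_line <- i
      next
    }
    if (!in_term) next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) {
      stop(sprintf("malformed line %d in OBO file: '%s'", i, lines[i]),
           call. = FALSE)
    }
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$id <- canonical_term_id(val)
    else if (key == "name") cur$name <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, canonical_term_id(val))
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, canonical_term_id(val))
    else if (key == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
  }
  if (in_term) stash(flush_term(cur, start_line))

  if (anyDuplicated(terms)) {
    stop("duplicate term ids: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "), call. = FALSE)
  }
  # Drop is_a edges pointing outside the retained term set (e.g. to obsolete
  # or truncated terms) rather than failing the whole parse.
  for (t in terms) {
    keep <- parents[[t]] %in% terms
    if (!all(keep)) {
      warning(sprintf("term %s: dropping is_a edge(s) to unknown term(s) %s",
                      t, paste(parents[[t]][!keep], collapse = ", ")),
              call. = FALSE)
      parents[[t]] <- parents[[t]][keep]
    }
  }
  alt_map <- unlist(alt_pairs)
  if (is.null(alt_map)) alt_map <- stats::setNames(character(0), character(0))
  new_ontology(terms, parents, labels, alt_map)
}

#' @export
print.ontology <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, integer(1)))
  cat(sprintf("<ontology> %d terms, %d is_a edges, %d alt ids\n",
              length(x$terms), n_edges, length(x$alt_map)))
  invisible(x)
}

#' Ancestors of a term
#'
#' Reflexive-transitive closure over `is_a` edges: the result always contains
#' the query term itself and the ontology root(s).
#'
#' @param ont an `ontology` (from [parse_obo()]).
#' @param term a single term identifier (alternate ids accepted).
#' @return sorted character vector of ancestor term ids, including `term`.
#' @export
term_ancestors <- function(ont, term) {
  term <- resolve_terms(ont, term)
  stopifnot(length(term) == 1L)
  ont$anc[[term]]
}

#' Descendants of a term
#'
#' Reflexive-transitive closure over inverted `is_a` edges; always contains
#' the query term. The reflexivity is what lets an exact term hit satisfy the
#' descendant-matching rule used by the diagnostic criteria.
#'
#' @inheritParams term_ancestors
#' @return sorted character vector of descendant term ids, including `term`.
#' @export
term_descendants <- function(ont, term) {
  term <- resolve_terms(ont, term)
  stopifnot(length(term) == 1L)
  ont$desc[[term]]
}

#' Read a disease-to-phenotype annotation table
#'
#' Expects a UTF-8 TSV with a header naming (at least) the columns
#' `disease_id` and `hpo_id`; lines starting with `#` are comments. Alternate
#' term ids are resolved to canonical form; rows whose term is absent from
#' the ontology are dropped with a warning; diseases left without any term
#' are removed. Duplicate (disease, term) rows collapse under set semantics.
#'
#' @param path path to the TSV file.
#' @param ont the companion `ontology` (from [parse_obo()]).
#' @return an object of class `"disease_annotations"`: a named list mapping
#'   disease id to a sorted character vector of canonical term ids.
#' @examples
#' obo <- system.file("extdata", "mini_hp.obo", package = "gorlin")
#' tsv <- system.file("extdata", "mini_annotations.tsv", package = "gorlin")
#' ont <- parse_obo(obo)
#' ann <- read_annotations(tsv, ont)
#' length(ann)
#' @export
read_annotations <- function(path, ont) {
  stopifnot(inherits(ont, "ontology"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("disease_id", "hpo_id") %in% names(df))) {
    stop("annotation table must have columns 'disease_id' and 'hpo_id'",
         call. = FALSE)
  }
  resolved <- resolve_terms(ont, df$hpo_id, strict = FALSE)
  if (anyNA(resolved)) {
    dropped <- unique(canonical_term_id(df$hpo_id[is.na(resolved)]))
    warning("dropping annotation rows with term(s) absent from ontology: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(resolved)
  ann <- split(resolved[keep], df$disease_id[keep])
  ann <- lapply(ann, function(x) sort(unique(x)))
  ann <- ann[vapply(ann, length, integer(1)) > 0]
  structure(ann[order(names(ann))], class = "disease_annotations")
}

#' @export
print.disease_annotations <- function(x, ...) {
  cat(sprintf("<disease_annotations> %d diseases, %d (disease, term) pairs\n",
              length(x), sum(vapply(x, length, integer(1)))))
  invisible(x)
}

#' Annotation-frequency information content
#'
#' For each term \eqn{t}, \eqn{p(t)} is the fraction of diseases annotated to
#' \eqn{t} or to any of its descendants, and \eqn{IC(t) = -\ln p(t)} (nats).
#' The root therefore has IC 0, IC is monotone non-decreasing from parent to
#' child, and terms with no (direct or propagated) annotation are omitted
#' rather than assigned infinite IC; similarity queries treat a missing IC
#' as 0 so that unannotated ancestors never dominate a MICA search.
#'
#' @param annotations a [read_annotations()] table.
#' @param ont the companion `ontology` (from [parse_obo()]).
#' @return a named numeric vector of class `"ic_table"` (nats).
#' @export
information_content <- function(annotations, ont) {
  stopifnot(inherits(annotations, "disease_annotations"),
            inherits(ont, "ontology"))
  if (length(annotations) == 0) stop("empty annotation table", call. = FALSE)
  counts <- stats::setNames(integer(length(ont$terms)), ont$terms)
  for (terms in annotations) {
    hit <- unique(unlist(ont$anc[terms], use.names = FALSE))
    counts[hit] <- counts[hit] + 1L
  }
  counts <- counts[counts > 0L]
  ic <- -log(counts / length(annotations))
  structure(ic, class = "ic_table")
}

#' Write an ontology back to OBO
#'
#' Emits a minimal OBO 1.2 document (id, name, alt_id, is_a) with terms in
#' sorted order; round-tripping through [parse_obo()] reproduces the same
#' ontology. Mainly used for fixtures and structural tests.
#'
#' @param ont an `ontology` (from [parse_obo()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  out <- c("format-version: 1.2", "")
  alt_by_canonical <- split(names(ont$alt_map), ont$alt_map)
  for (t in ont$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", ont$labels[[t]]))
    for (a in sort(alt_by_canonical[[t]])) out <- c(out, paste0("alt_id: ", a))
    for (p in sort(ont$parents[[t]])) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
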