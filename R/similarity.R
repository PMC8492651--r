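#' Resnik similarity between two terms
#'
#' IC of the most informative common ancestor (MICA). Returns 0 when the only
#' shared ancestor is the root, or when no common ancestor carries an IC
#' entry (missing IC is treated as 0 by design; see the package vignette).
#'
#' @param t1,t2 term identifiers.
#' @param ont an `ontology` (from [parse_obo()]).
#' @param ic an [information_content()] table.
#' @return a single non-negative similarity (nats).
#' @export
resnik_term_sim <- function(t1, t2, ont, ic) {
  t1 <- resolve_terms(ont, t1); t2 <- resolve_terms(ont, t2)
  common <- intersect(ont$anc[[t1]], ont$anc[[t2]])
  vals <- unclass(ic)[common]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(0)
  max(0, max(vals))
}

#' Resnik similarity between two phenotype profiles
#'
#' Aggregates pairwise term similarities across two term sets. The default
#' `"bma"` (symmetric best-match average) averages, for each term of one
#' profile, its best match in the other, then averages the two directions;
#' it is symmetric by construction. `"max"` takes the single best pair and
#' `"mean-pairwise"` averages the full similarity matrix.
#'
#' @param p1,p2 nonempty character vectors of term ids.
#' @param ont an `ontology` (from [parse_obo()]).
#' @param ic an [information_content()] table.
#' @param method `"bma"` (default), `"max"`, or `"mean-pairwise"`.
#' @return a single non-negative similarity (nats).
#' @export
profile_similarity <- function(p1, p2, ont, ic,
                               method = c("bma", "max", "mean-pairwise")) {
  method <- match.arg(method)
  if (length(p1) == 0 || length(p2) == 0) {
    stop("profiles must be nonempty", call. = FALSE)
  }
  p1 <- unique(resolve_terms(ont, p1))
  p2 <- unique(resolve_terms(ont, p2))
  simmat <- outer(seq_along(p1), seq_along(p2),
                  Vectorize(function(i, j) resnik_term_sim(p1[i], p2[j], ont, ic)))
  switch(method,
         "bma" = (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2,
         "max" = max(simmat),
         "mean-pairwise" = mean(simmat))
}

#' Rank diseases by similarity to a target phenotype profile
#'
#' Scores every disease profile in an annotation table against the target
#' term set and returns the top `k`, sorted by descending score with ties
#' broken by ascending disease id so the selection is reproducible under any
#' input ordering.
#'
#' @param target nonempty character vector of term ids.
#' @param annotations a [read_annotations()] table.
#' @param ont an `ontology` (from [parse_obo()]).
#' @param ic an [information_content()] table.
#' @param k number of diseases to return.
#' @param exclude disease ids to leave out of the ranking (typically the
#'   target disease itself, when it is present in the table).
#' @param method aggregation passed to [profile_similarity()].
#' @return data.frame with columns `rank`, `disease_id`, `score`.
#' @examples
#' obo <- system.file("extdata", "mini_hp.obo", package = "gorlin")
#' tsv <- system.file("extdata", "mini_annotations.tsv", package = "gorlin")
#' ont <- parse_obo(obo)
#' ann <- read_annotations(tsv, ont)
#' ic <- information_content(ann, ont)
#' most_similar_diseases(nbccs_target_profile(), ann, ont, ic, k = 5,
#'                       exclude = "OMIM:109400")
#' @export
most_similar_diseases <- function(target, annotations, ont, ic, k,
                                  exclude = character(0),
                                  method = "bma") {
  stopifnot(inherits(annotations, "disease_annotations"))
  if (length(target) == 0) stop("target profile must be nonempty", call. = FALSE)
  pool <- setdiff(names(annotations), exclude)
  if (k > length(pool)) {
    stop(sprintf("k = %d exceeds the %d available diseases", k, length(pool)),
         call. = FALSE)
  }
  scores <- vapply(pool, function(d) {
    profile_similarity(target, annotations[[d]], ont, ic, method = method)
  }, numeric(1))
  ord <- order(-scores, pool)
  top <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), disease_id = pool[top],
             score = unname(scores[top]), stringsAsFactors = FALSE)
}

#' Default NBCCS target profile
#'
#' The union of every HP term appearing in either criteria encoding
#' ([existing_criteria_definition()] and [proposed_criteria_definition()]),
#' used as the query profile when ranking OMIM diseases by similarity to
#' NBCCS. Configurable: pass any term set to [most_similar_diseases()].
#'
#' @return character vector of canonical term ids.
#' @export
nbccs_target_profile <- function() {
  defs <- list(existing_criteria_definition(), proposed_criteria_definition())
  terms <- unlist(lapply(defs, function(d) {
    unlist(lapply(d$tiers, function(tier) {
      unlist(lapply(tier$groups, `[[`, "terms"), use.names = FALSE)
    }), use.names = FALSE)
  }), use.names = FALSE)
  sort(unique(terms))
}
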