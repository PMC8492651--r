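#' Simulate one control individual from a disease annotation profile
#'
#' Draws a feature count k uniformly from 1..K (K = number of terms
#' annotated to the disease), then samples k distinct annotated terms
#' uniformly without replacement. Uses the current RNG state; seed at the
#' cohort level ([simulate_cohort()]) for reproducibility.
#'
#' @param disease_id a disease present in `annotations`.
#' @param annotations a [read_annotations()] table.
#' @return object of class `"simulated_individual"` with fields
#'   `disease_id` and `present_terms`.
#' @export
simulate_individual <- function(disease_id, annotations) {
  stopifnot(inherits(annotations, "disease_annotations"))
  terms <- annotations[[disease_id]]
  if (is.null(terms)) stop("unknown disease: ", disease_id, call. = FALSE)
  k <- sample.int(length(terms), 1L)
  structure(
    list(disease_id = disease_id,
         present_terms = sort(sample(terms, k, replace = FALSE))),
    class = "simulated_individual"
  )
}

#' Simulate a Monte Carlo control cohort
#'
#' Each individual's disease is drawn uniformly from `disease_subset`
#' (default: every disease in the table), then its features are sampled by
#' [simulate_individual()]. With the same seed and inputs the cohort is
#' bit-identical.
#'
#' @param annotations a [read_annotations()] table.
#' @param n number of individuals (0 allowed).
#' @param disease_subset optional character vector of disease ids to draw
#'   from (e.g. the top-500 most similar diseases).
#' @param seed optional integer seed (applied locally; the caller's RNG
#'   state is untouched).
#' @return list of `"simulated_individual"` objects, length `n`.
#' @export
simulate_cohort <- function(annotations, n, disease_subset = NULL, seed = NULL) {
  stopifnot(inherits(annotations, "disease_annotations"), n >= 0)
  if (is.null(disease_subset)) disease_subset <- names(annotations)
  if (length(disease_subset) == 0) stop("empty disease subset", call. = FALSE)
  missing <- setdiff(disease_subset, names(annotations))
  if (length(missing) > 0) {
    stop("subset diseases absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  run <- function() {
    lapply(seq_len(n), function(i) {
      d <- disease_subset[sample.int(length(disease_subset), 1L)]
      simulate_individual(d, annotations)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

profile_terms <- function(ind) {
  if (inherits(ind, "simulated_individual")) return(ind$present_terms)
  if (inherits(ind, "participant_profile")) return(ind$features$term)
  stop("expected a simulated_individual or participant_profile", call. = FALSE)
}

#' Descendant-aware feature presence
#'
#' TRUE when the individual's term list intersects the reflexive descendant
#' closure of `term`: the query term itself, or anything below it in the
#' ontology, counts as present.
#'
#' @param ind a `"simulated_individual"` or [participant_profile()].
#' @param term a term identifier.
#' @param ont an `ontology` (from [parse_obo()]).
#' @return logical scalar.
#' @export
has_feature <- function(ind, term, ont) {
  term <- resolve_terms(ont, term)
  present <- profile_terms(ind)
  if (length(present) == 0) return(FALSE)
  present <- resolve_terms(ont, present)
  any(vapply(present, function(p) term %in% ont$anc[[p]], logical(1)))
}

#' Write / read simulated cohorts as TSV
#'
#' Columns: `individual_id`, `disease_id`, `terms` (semicolon-joined HP ids).
#'
#' @param cohort list of `"simulated_individual"` objects.
#' @param path file path.
#' @return `path` (writer) or the cohort list (reader), invisibly/visibly.
#' @export
write_simulated_cohort <- function(cohort, path) {
  df <- data.frame(
    individual_id = sprintf("SIM%06d", seq_along(cohort)),
    disease_id = vapply(cohort, `[[`, character(1), "disease_id"),
    terms = vapply(cohort, function(x) paste(x$present_terms, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_simulated_cohort
#' @export
read_simulated_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(disease_id = df$disease_id[i],
                   present_terms = strsplit(df$terms[i], ";", fixed = TRUE)[[1]]),
              class = "simulated_individual")
  })
}
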