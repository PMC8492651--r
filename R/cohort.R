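#' Construct a feature specification for cohort synthesis
#'
#' One clinical feature of the synthetic cohort: a representative HP term, a
#' marginal prevalence, and an onset model — either congenital (point mass
#' at 0 months) or lognormal parameterized by its median in months with a
#' fixed log-scale spread.
#'
#' @param label human-readable feature name.
#' @param term representative term id for the matching criteria group.
#' @param prevalence probability in \[0, 1\] that a participant has the feature.
#' @param median_onset_months median onset for the lognormal model (ignored
#'   when `congenital`).
#' @param congenital logical; congenital features onset at 0 months always.
#' @param sigma lognormal log-scale standard deviation (default 0.6).
#' @return object of class `"feature_spec"`.
#' @export
feature_spec <- function(label, term, prevalence, median_onset_months = NA_real_,
                         congenital = FALSE, sigma = 0.6) {
  stopifnot(prevalence >= 0, prevalence <= 1, sigma > 0)
  if (!congenital && prevalence > 0 && (is.na(median_onset_months) || median_onset_months <= 0)) {
    stop("non-congenital features need a positive median onset", call. = FALSE)
  }
  structure(list(label = label, term = canonical_term_id(term),
                 prevalence = prevalence,
                 median_onset_months = median_onset_months,
                 congenital = isTRUE(congenital), sigma = sigma),
            class = "feature_spec")
}

#' Default synthetic-cohort configuration
#'
#' Emulates the 48-participant NBCCS survey cohort: per-feature prevalences
#' and median onset ages transcribed from the published feature table
#' (prevalence as a fraction of 48; onsets in months; congenital features at
#' 0 months), a 25% rate of affected first-degree relatives, and a 40% rate
#' of molecular diagnoses. Ovarian/cardiac fibroma is included at prevalence
#' 0 (never reported). Features are sampled independently per participant —
#' marginals are calibrated, joint structure is not.
#'
#' @param n_participants cohort size (default 48).
#' @param seed default seed recorded in the config (overridable at
#'   generation time).
#' @return object of class `"cohort_config"`.
#' @export
default_cohort_config <- function(n_participants = 48L, seed = 20211005L) {
  specs <- list(
    feature_spec("Jaw keratocysts", "HP:0010603", 0.69, 120),
    feature_spec("Palmar or plantar pitting", "HP:0010610", 0.69, 89),
    feature_spec("Basal cell carcinoma", "HP:0002671", 0.69, 170),
    feature_spec("Calcification of falx cerebri", "HP:0005462", 0.29, 174),
    feature_spec("Medulloblastoma", "HP:0002885", 0.06, 10),
    feature_spec("Macrocephaly", "HP:0000256", 0.58, 1),
    feature_spec("Ocular abnormalities", "HP:0000518", 0.21, congenital = TRUE),
    feature_spec("Cleft lip/palate", "HP:0000175", 0.10, congenital = TRUE),
    feature_spec("Rib anomalies", "HP:0000772", 0.42, congenital = TRUE),
    feature_spec("Skeletal malformations", "HP:0000925", 0.46, congenital = TRUE),
    feature_spec("Ovarian or cardiac fibroma", "HP:0010618", 0.00, congenital = TRUE)
  )
  structure(list(n_participants = as.integer(n_participants),
                 feature_specs = specs,
                 p_family_history = 0.25,
                 p_molecular_dx = 0.40,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, %d feature specs, P(family history) = %.2f\n",
              x$n_participants, length(x$feature_specs), x$p_family_history))
  invisible(x)
}

#' Sample an onset age from a feature specification
#'
#' Congenital features return 0. Otherwise a lognormal draw with median
#' `median_onset_months` (meanlog = log(median)) and sdlog `sigma`, rounded
#' to whole months and clamped to \[0, 216\]. Uses the current RNG state.
#'
#' @param spec a [feature_spec()].
#' @return integer onset age in months.
#' @export
sample_onset <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  if (spec$congenital) return(0L)
  draw <- stats::rlnorm(1, meanlog = log(spec$median_onset_months),
                        sdlog = spec$sigma)
  as.integer(min(216L, max(0L, round(draw))))
}

#' Generate a synthetic survey cohort
#'
#' Every participant draws each feature independently with its configured
#' prevalence; present features receive onset ages from [sample_onset()];
#' family-history and molecular-diagnosis flags are independent Bernoulli
#' draws. Seed-deterministic.
#'
#' @param config a [default_cohort_config()]-style configuration.
#' @param seed optional integer seed; defaults to `config$seed`.
#' @return list of [participant_profile()] objects, length
#'   `config$n_participants`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  run <- function() {
    lapply(seq_len(config$n_participants), function(i) {
      terms <- character(0); onsets <- integer(0)
      for (spec in config$feature_specs) {
        if (stats::runif(1) < spec$prevalence) {
          terms <- c(terms, spec$term)
          onsets <- c(onsets, sample_onset(spec))
        }
      }
      participant_profile(
        id = sprintf("SYN%03d", i), terms = terms, onset_months = onsets,
        family_history = stats::runif(1) < config$p_family_history,
        molecular_dx = stats::runif(1) < config$p_molecular_dx
      )
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read / write participant cohorts as TSV
#'
#' Dialect: `participant_id`, `hpo_id`, `onset_months` (integer or NA),
#' `family_history` (0/1), `molecular_dx` (0/1); one row per feature, flags
#' repeated on each of a participant's rows. A participant without features
#' is encoded as a single row with an empty `hpo_id`.
#'
#' @param cohort list of [participant_profile()] objects.
#' @param path file path.
#' @param ont optional `ontology` (from [parse_obo()]) used to resolve alternate ids on read.
#' @return `path` (writer) / list of profiles (reader).
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    if (nrow(p$features) == 0) {
      data.frame(participant_id = p$id, hpo_id = "",
                 onset_months = NA_integer_,
                 family_history = as.integer(p$family_history),
                 molecular_dx = as.integer(p$molecular_dx),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(participant_id = p$id, hpo_id = p$features$term,
                 onset_months = p$features$onset_months,
                 family_history = as.integer(p$family_history),
                 molecular_dx = as.integer(p$molecular_dx),
                 stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, ont = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(participant_id = "character",
                                         hpo_id = "character"))
  need <- c("participant_id", "hpo_id", "onset_months", "family_history",
            "molecular_dx")
  if (!all(need %in% names(df))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$participant_id), function(rows) {
    keep <- !is.na(rows$hpo_id) & nzchar(rows$hpo_id)
    terms <- rows$hpo_id[keep]
    if (!is.null(ont) && length(terms)) terms <- resolve_terms(ont, terms)
    participant_profile(
      id = rows$participant_id[1], terms = terms,
      onset_months = as.integer(rows$onset_months[keep]),
      family_history = rows$family_history[1] == 1,
      molecular_dx = rows$molecular_dx[1] == 1
    )
  })
}
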