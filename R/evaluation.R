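#' Age-resolved sensitivity curve
#'
#' Fraction of the cohort meeting the criteria at each month from birth to
#' 18 years (ages 0..216, 217 points). Because features only accumulate
#' with age, the curve is non-decreasing; it is computed by thresholding
#' each participant's [age_first_met()] and cross-checked in the test suite
#' against a brute-force monthly re-evaluation.
#'
#' @param cohort nonempty list of [participant_profile()] objects.
#' @param defn a `"criteria_definition"`.
#' @param ont an `ontology` (from [parse_obo()]).
#' @param use_family_history,use_molecular passed to [meets_criteria()].
#' @return object of class `"sensitivity_curve"`: data.frame with columns
#'   `age_months` (0..216) and `sensitivity`, with the criteria label and
#'   flag settings as attributes.
#' @export
sensitivity_curve <- function(cohort, defn, ont, use_family_history = FALSE,
                              use_molecular = FALSE) {
  if (length(cohort) == 0) stop("empty cohort", call. = FALSE)
  first <- vapply(cohort, age_first_met, integer(1), defn = defn, ont = ont,
                  use_family_history = use_family_history,
                  use_molecular = use_molecular)
  ages <- 0:216
  sens <- vapply(ages, function(m) mean(!is.na(first) & first <= m), numeric(1))
  structure(data.frame(age_months = ages, sensitivity = sens),
            class = c("sensitivity_curve", "data.frame"),
            criteria_label = defn$label,
            family_history_used = use_family_history,
            molecular_used = use_molecular)
}

#' Median age at meeting the criteria
#'
#' Median over participants of [age_first_met()], with participants who
#' never meet the criteria by 18 years treated as +Inf. For even cohort
#' sizes the lower of the two central order statistics is used (documented
#' convention). Returns `NA` when more than half the cohort never meets the
#' criteria (the median itself would be infinite).
#'
#' @inheritParams sensitivity_curve
#' @return integer months, or `NA_integer_`.
#' @export
median_age_at_criteria <- function(cohort, defn, ont, use_family_history = FALSE,
                                   use_molecular = FALSE) {
  if (length(cohort) == 0) stop("empty cohort", call. = FALSE)
  first <- vapply(cohort, age_first_met, integer(1), defn = defn, ont = ont,
                  use_family_history = use_family_history,
                  use_molecular = use_molecular)
  ages <- sort(ifelse(is.na(first), Inf, as.numeric(first)))
  med <- ages[floor((length(ages) + 1) / 2)]  # lower median for even n
  if (is.infinite(med)) NA_integer_ else as.integer(med)
}

#' Monte Carlo specificity against simulated controls
#'
#' Every simulated control is evaluated age-free (`at_age = "any"`: OMIM
#' annotations carry no onset, so specificity is assessed "at adulthood")
#' with family history and molecular diagnosis off. Specificity is
#' TN / (TN + FP).
#'
#' @param controls nonempty list of `"simulated_individual"` objects.
#' @param defn a `"criteria_definition"`.
#' @param ont an `ontology` (from [parse_obo()]).
#' @return object of class `"specificity_result"`: list with `n_controls`,
#'   `true_negatives`, `false_positives`, `specificity`.
#' @export
specificity <- function(controls, defn, ont) {
  if (length(controls) == 0) stop("empty control set", call. = FALSE)
  fp <- 0L
  for (ind in controls) {
    prof <- participant_profile(ind$disease_id, terms = ind$present_terms)
    if (meets_criteria(prof, defn, ont, at_age_months = "any",
                       use_family_history = FALSE, use_molecular = FALSE)) {
      fp <- fp + 1L
    }
  }
  n <- length(controls)
  structure(list(n_controls = n, true_negatives = n - fp,
                 false_positives = fp, specificity = (n - fp) / n),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result> %d controls: TN = %d, FP = %d, specificity = %.4f\n",
              x$n_controls, x$true_negatives, x$false_positives, x$specificity))
  invisible(x)
}

#' Run the full evaluation pipeline
#'
#' Orchestrates: disease ranking (Resnik top-k) -> control simulation ->
#' optional classifier training/CV -> age-resolved sensitivity for both
#' criteria on a participant cohort -> Monte Carlo specificity. Every stage
#' is seeded from `config$seed` so two runs with the same config are
#' identical.
#'
#' @param config list with elements: `ontology` (path to OBO), `annotations`
#'   (path to TSV), `cohort` (path to a cohort TSV, or `"synthetic"`),
#'   `k` (diseases to keep, default `min(500, available)`), `n_controls`
#'   (default 5000), `seed` (default 1), `criteria_rule` (`"methods"` or
#'   `"table2"`), `use_family_history` / `use_molecular` (defaults FALSE),
#'   `train_classifier` (default FALSE), `target_disease` (disease id
#'   excluded from ranking, default `"OMIM:109400"`), and optional `out_dir`
#'   to write the report JSON plus curve/ranking TSVs.
#' @return report list (invisibly written to `out_dir` when given) with
#'   parameters, ranked diseases, specificity counts, sensitivity curves and
#'   (optionally) cross-validation metrics.
#' @export
run_pipeline <- function(config) {
  need <- c("ontology", "annotations", "cohort")
  if (!all(need %in% names(config))) {
    stop("config must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  rule <- if (is.null(config$criteria_rule)) "methods" else config$criteria_rule
  ufh <- isTRUE(config$use_family_history)
  umol <- isTRUE(config$use_molecular)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ont <- stage("ontology", parse_obo(config$ontology))
  ann <- stage("annotations", read_annotations(config$annotations, ont))
  ic <- stage("information-content", information_content(ann, ont))

  target_disease <- if (is.null(config$target_disease)) "OMIM:109400" else config$target_disease
  k <- if (is.null(config$k)) min(500L, length(ann) - (target_disease %in% names(ann))) else config$k
  ranked <- stage("rank-diseases",
                  most_similar_diseases(nbccs_target_profile(), ann, ont, ic,
                                        k = k, exclude = target_disease))

  n_controls <- if (is.null(config$n_controls)) 5000L else as.integer(config$n_controls)
  controls <- stage("simulate-controls",
                    simulate_cohort(ann, n_controls,
                                    disease_subset = ranked$disease_id,
                                    seed = seed))

  cohort <- stage("cohort", {
    if (identical(config$cohort, "synthetic")) {
      generate_cohort(default_cohort_config(), seed = seed + 1L)
    } else {
      read_cohort(config$cohort, ont)
    }
  })

  existing <- existing_criteria_definition(rule)
  proposed <- proposed_criteria_definition()

  curves <- stage("sensitivity", list(
    existing = sensitivity_curve(cohort, existing, ont, ufh, umol),
    proposed = sensitivity_curve(cohort, proposed, ont, ufh, umol)
  ))
  specs <- stage("specificity", list(
    existing = specificity(controls, existing, ont),
    proposed = specificity(controls, proposed, ont)
  ))

  report <- list(
    parameters = list(seed = seed, k = k, n_controls = n_controls,
                      criteria_rule = rule, use_family_history = ufh,
                      use_molecular = umol, cohort = config$cohort,
                      target_disease = target_disease,
                      n_participants = length(cohort)),
    ranked_diseases = ranked,
    specificity = list(
      existing = unclass(specs$existing),
      proposed = unclass(specs$proposed)
    ),
    median_age_months = list(
      existing = median_age_at_criteria(cohort, existing, ont, ufh, umol),
      proposed = median_age_at_criteria(cohort, proposed, ont, ufh, umol)
    ),
    curves = data.frame(age_months = curves$existing$age_months,
                        sensitivity_existing = curves$existing$sensitivity,
                        sensitivity_proposed = curves$proposed$sensitivity)
  )

  if (isTRUE(config$train_classifier)) {
    report$cross_validation <- stage("train-nbc", {
      cv <- nbc_cross_validate(cohort, controls, default_vocabulary(), ont,
                               folds = min(10L, length(cohort)), seed = seed + 2L)
      cv$mean
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$curves,
                       file.path(config$out_dir, "sensitivity_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ranked, file.path(config$out_dir, "ranked_diseases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json <- report
    json$curves <- NULL; json$ranked_diseases <- NULL
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
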