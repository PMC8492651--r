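#' Construct a term group
#'
#' A term group is an "or"-list of HP terms: a patient profile satisfies the
#' group when any profile feature equals a member term or lies below it in
#' the ontology (descendant matching).
#'
#' @param terms nonempty character vector of term ids.
#' @param label short human-readable label.
#' @return object of class `"term_group"`.
#' @export
term_group <- function(terms, label) {
  stopifnot(length(terms) >= 1, is.character(label), nchar(label) > 0)
  structure(list(terms = canonical_term_id(terms), label = label),
            class = "term_group")
}

#' Construct a participant profile
#'
#' One (real or synthetic) patient: phenotype features with onset ages in
#' months, plus family-history and molecular-diagnosis flags. Onset 0
#' encodes congenital/prenatal; an `NA` onset means the feature was reported
#' without an age — such features count in age-free (`at_age = "any"`)
#' evaluation but are excluded at every finite age.
#'
#' @param id participant identifier.
#' @param terms character vector of feature term ids (may be empty).
#' @param onset_months integer vector, same length as `terms`; `NA` allowed.
#' @param family_history logical: affected first-degree relative.
#' @param molecular_dx logical: molecular diagnosis established.
#' @return object of class `"participant_profile"`.
#' @export
participant_profile <- function(id, terms = character(0),
                                onset_months = rep(NA_integer_, length(terms)),
                                family_history = FALSE, molecular_dx = FALSE) {
  stopifnot(length(onset_months) == length(terms),
            is.logical(family_history), is.logical(molecular_dx))
  onset_months <- as.integer(onset_months)
  if (any(onset_months < 0, na.rm = TRUE)) {
    stop("onset ages must be >= 0 months", call. = FALSE)
  }
  terms <- if (length(terms)) canonical_term_id(terms) else character(0)
  structure(
    list(id = as.character(id),
         features = data.frame(term = terms, onset_months = onset_months,
                               stringsAsFactors = FALSE),
         family_history = isTRUE(family_history),
         molecular_dx = isTRUE(molecular_dx)),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("<participant_profile> %s: %d features, family history %s, molecular dx %s\n",
              x$id, nrow(x$features), x$family_history, x$molecular_dx))
  invisible(x)
}

new_criteria_definition <- function(kind, label, tiers, rule, family_history_role) {
  all_groups <- unlist(lapply(tiers, function(t) {
    vapply(t$groups, function(g) paste(sort(g$terms), collapse = ","), character(1))
  }))
  if (anyDuplicated(all_groups)) {
    stop("a term group appears twice in the criteria definition", call. = FALSE)
  }
  structure(list(kind = kind, label = label, tiers = tiers, rule = rule,
                 family_history_role = family_history_role),
            class = "criteria_definition")
}

#' @export
print.criteria_definition <- function(x, ...) {
  cat(sprintf("<criteria_definition> %s (%s)\n", x$label, x$kind))
  for (tier in x$tiers) {
    cat(sprintf("  %s (weight %s): %d group(s)\n", tier$name,
                ifelse(is.na(tier$weight), "-", tier$weight), length(tier$groups)))
  }
  invisible(x)
}

#' Existing NBCCS diagnostic criteria (major/minor scheme)
#'
#' Machine encoding of the consensus criteria: four coded major-feature
#' groups (jaw keratocysts, palmoplantar pits, falx calcification, basal
#' cell carcinoma) plus an affected first-degree relative counting as a
#' fifth major slot, and six minor-feature groups (medulloblastoma,
#' macrocephaly, oral cleft, polydactyly, skeletal/rib anomalies, ocular
#' abnormalities). Ovarian/cardiac fibroma and lymphomesenteric cysts are
#' not encoded (never reported in the calibration cohort, and absent from
#' the coded term list).
#'
#' Two published decision-rule variants exist and both are provided:
#' \describe{
#'   \item{`"methods"` (default)}{diagnosis at 2 majors + 1 minor, or
#'     1 major + 3 minors.}
#'   \item{`"table2"`}{diagnosis at 1 major + molecular diagnosis, 2 majors,
#'     or 1 major + 2 minors.}
#' }
#'
#' @param rule decision-rule variant, `"methods"` or `"table2"`.
#' @return a `"criteria_definition"` of kind `"major_minor"`.
#' @export
existing_criteria_definition <- function(rule = c("methods", "table2")) {
  rule <- match.arg(rule)
  majors <- list(
    term_group("HP:0010603", "Odontogenic keratocysts of the jaw"),
    term_group("HP:0010610", "Palmoplantar pits"),
    term_group("HP:0005462", "Calcification of the falx cerebri"),
    term_group("HP:0002671", "Basal cell carcinoma")
  )
  minors <- list(
    term_group("HP:0002885", "Medulloblastoma"),
    term_group("HP:0000256", "Macrocephaly"),
    term_group(c("HP:0000175", "HP:0410030"), "Oral cleft"),
    term_group("HP:0010442", "Polydactyly"),
    term_group(c("HP:0000925", "HP:0000772"), "Skeletal or rib anomaly"),
    term_group(c("HP:0000518", "HP:0000589", "HP:0000568", "HP:0008058"),
               "Ocular abnormality")
  )
  combos <- switch(rule,
    methods = list(c(major = 2L, minor = 1L), c(major = 1L, minor = 3L)),
    table2  = list(c(major = 2L, minor = 0L), c(major = 1L, minor = 2L))
  )
  new_criteria_definition(
    kind = "major_minor",
    label = paste0("existing-", rule),
    tiers = list(
      list(name = "major", groups = majors, weight = NA_integer_),
      list(name = "minor", groups = minors, weight = NA_integer_)
    ),
    rule = list(variant = rule, combos = combos,
                molecular_combo = c(major = 1L)),
    family_history_role = "counts_as_major"
  )
}

#' Proposed pediatric NBCCS criteria (point-based scheme)
#'
#' Three tiers of descendant-aware feature groups: cardinal features score
#' 3 points (jaw cysts, palmoplantar pits, falx calcification, basal cell
#' carcinoma, rib anomaly, congenital eye abnormality), suggestive features
#' 2 points (medulloblastoma, macrocephaly, vertebral/skeletal anomaly), and
#' possible features 1 point (tall stature, structural brain anomaly,
#' strabismus, natal teeth, oral cleft, genitourinary anomaly, hearing
#' impairment). Molecular testing is recommended at a total of 6 or more
#' points; an affected first-degree relative triggers the recommendation on
#' its own, independent of the point total. Parenthesized clinical
#' qualifiers of the published table (centiles, SHH subtype) are advisory
#' only and deliberately not encoded.
#'
#' @return a `"criteria_definition"` of kind `"points"`.
#' @export
proposed_criteria_definition <- function() {
  cardinal <- list(
    term_group("HP:0010603", "Odontogenic keratocysts of the jaw"),
    term_group("HP:0010610", "Palmoplantar pits"),
    term_group("HP:0005462", "Calcification of the falx cerebri"),
    term_group("HP:0002671", "Basal cell carcinoma"),
    term_group("HP:0000772", "Rib anomaly"),
    term_group(c("HP:0000518", "HP:0000589", "HP:0000568", "HP:0008058"),
               "Congenital structural eye abnormality")
  )
  suggestive <- list(
    term_group("HP:0002885", "Medulloblastoma"),
    term_group("HP:0000256", "Macrocephaly"),
    term_group("HP:0000925", "Skeletal (vertebral) anomaly")
  )
  possible <- list(
    term_group("HP:0000098", "Tall stature"),
    term_group(c("HP:0002119", "HP:0002126", "HP:0002308", "HP:0100702"),
               "Structural brain anomaly"),
    term_group("HP:0000486", "Strabismus"),
    term_group("HP:0000695", "Natal teeth"),
    term_group(c("HP:0000175", "HP:0410030"), "Oral cleft"),
    term_group(c("HP:0000107", "HP:0000104"), "Genitourinary anomaly"),
    term_group("HP:0000365", "Hearing impairment")
  )
  new_criteria_definition(
    kind = "points",
    label = "proposed-points",
    tiers = list(
      list(name = "cardinal", groups = cardinal, weight = 3L),
      list(name = "suggestive", groups = suggestive, weight = 2L),
      list(name = "possible", groups = possible, weight = 1L)
    ),
    rule = list(threshold = 6L),
    family_history_role = "standalone_trigger"
  )
}

# For every group of the definition, whether any profile feature matches it
# (ignoring onset) and the earliest known onset among matching features
# (Inf when no matching feature has a known onset).
profile_group_onsets <- function(profile, defn, ont) {
  feats <- profile$features
  n <- nrow(feats)
  anc <- if (n > 0) ont$anc[resolve_terms(ont, feats$term)] else list()
  res <- list()
  for (tier in defn$tiers) {
    for (g in tier$groups) {
      matched <- logical(n)
      for (i in seq_len(n)) matched[i] <- any(g$terms %in% anc[[i]])
      known <- matched & !is.na(feats$onset_months)
      res[[length(res) + 1L]] <- list(
        tier = tier$name, weight = tier$weight, label = g$label,
        matched_any = any(matched),
        earliest = if (any(known)) min(feats$onset_months[known]) else Inf
      )
    }
  }
  res
}

group_active <- function(info, at_age) {
  if (identical(at_age, "any")) return(info$matched_any)
  info$earliest <= at_age
}

#' Is a term group satisfied by a profile?
#'
#' TRUE when some profile feature equals a group member term or one of its
#' ontology descendants, and — at a finite age — that feature's onset is
#' known and no later than `at_age_months`. At `"any"`, onset (including
#' unknown onset) is ignored.
#'
#' @param profile a [participant_profile()].
#' @param group a [term_group()].
#' @param ont an `ontology` (from [parse_obo()]).
#' @param at_age_months integer age in months, or `"any"`.
#' @return logical scalar.
#' @export
group_satisfied <- function(profile, group, ont, at_age_months = "any") {
  defn <- new_criteria_definition(
    "points", "single-group",
    list(list(name = "g", groups = list(group), weight = 1L)),
    list(threshold = 1L), "standalone_trigger"
  )
  info <- profile_group_onsets(profile, defn, ont)[[1]]
  group_active(info, at_age_months)
}

#' Point score under a point-based criteria definition
#'
#' Sums the tier weights of all satisfied groups; a group contributes its
#' weight at most once no matter how many profile features match it.
#'
#' @param profile a [participant_profile()].
#' @param ont an `ontology` (from [parse_obo()]).
#' @param at_age_months integer age in months, or `"any"`.
#' @param defn a point-based criteria definition (default: the proposed
#'   pediatric scheme).
#' @return integer point total.
#' @export
score_proposed <- function(profile, ont, at_age_months = "any",
                           defn = proposed_criteria_definition()) {
  stopifnot(identical(defn$kind, "points"))
  infos <- profile_group_onsets(profile, defn, ont)
  sum(vapply(infos, function(x) {
    if (group_active(x, at_age_months)) as.integer(x$weight) else 0L
  }, integer(1)))
}

#' Evaluate a criteria definition against a profile
#'
#' Point-based definitions are met when the point total reaches the
#' threshold, or — with `use_family_history` — when the profile reports an
#' affected first-degree relative (standalone trigger). Major/minor
#' definitions are met when any sufficient (n major, n minor) combination of
#' the decision rule holds; family history counts as a major criterion iff
#' `use_family_history`, and the 1-major-plus-molecular-diagnosis
#' combination is active iff `use_molecular`.
#'
#' @param profile a [participant_profile()].
#' @param defn a `"criteria_definition"`.
#' @param ont an `ontology` (from [parse_obo()]).
#' @param at_age_months integer age in months, or `"any"`.
#' @param use_family_history logical.
#' @param use_molecular logical.
#' @return logical scalar.
#' @export
meets_criteria <- function(profile, defn, ont, at_age_months = "any",
                           use_family_history = TRUE, use_molecular = TRUE) {
  infos <- profile_group_onsets(profile, defn, ont)
  meets_criteria_impl(profile, defn, infos, at_age_months,
                      use_family_history, use_molecular)
}

meets_criteria_impl <- function(profile, defn, infos, at_age_months,
                                use_family_history, use_molecular) {
  active <- vapply(infos, group_active, logical(1), at_age = at_age_months)
  if (defn$kind == "points") {
    if (use_family_history &&
        identical(defn$family_history_role, "standalone_trigger") &&
        profile$family_history) {
      return(TRUE)
    }
    score <- sum(vapply(infos[active], function(x) as.integer(x$weight), integer(1)))
    return(score >= defn$rule$threshold)
  }
  # major/minor scheme
  tiers <- vapply(infos, `[[`, character(1), "tier")
  n_major <- sum(active[tiers == "major"])
  if (use_family_history &&
      identical(defn$family_history_role, "counts_as_major") &&
      profile$family_history) {
    n_major <- n_major + 1L  # diagnosed relatives assumed known from birth
  }
  n_minor <- sum(active[tiers == "minor"])
  for (combo in defn$rule$combos) {
    if (n_major >= combo[["major"]] && n_minor >= combo[["minor"]]) return(TRUE)
  }
  if (use_molecular && profile$molecular_dx &&
      n_major >= defn$rule$molecular_combo[["major"]]) {
    return(TRUE)
  }
  FALSE
}

#' Earliest age at which a profile meets a criteria definition
#'
#' Scans ages 0..216 months (birth to 18 years). Family history, when used,
#' is assumed known at birth, so it contributes from month 0. Features with
#' unknown onset never contribute at a finite age. Implemented over the
#' candidate onset ages of the profile; equivalent to (and tested against) a
#' brute-force monthly scan because features only accumulate with age.
#'
#' @inheritParams meets_criteria
#' @param max_age_months upper scan bound (default 216).
#' @return smallest month at which the criteria are met, or `NA_integer_` if
#'   they are never met by `max_age_months`.
#' @export
age_first_met <- function(profile, defn, ont, use_family_history = TRUE,
                          use_molecular = TRUE, max_age_months = 216L) {
  infos <- profile_group_onsets(profile, defn, ont)
  onsets <- vapply(infos, `[[`, numeric(1), "earliest")
  candidates <- sort(unique(c(0, onsets[is.finite(onsets) & onsets <= max_age_months])))
  for (m in candidates) {
    if (meets_criteria_impl(profile, defn, infos, m,
                            use_family_history, use_molecular)) {
      return(as.integer(m))
    }
  }
  NA_integer_
}
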