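test_that("criteria definitions carry the published structure", {
  ex <- existing_criteria_definition()
  expect_equal(ex$kind, "major_minor")
  major <- ex$tiers[[1]]; minor <- ex$tiers[[2]]
  # 4 coded major groups; family history is the 5th major slot via its role
  expect_length(major$groups, 4)
  expect_equal(ex$family_history_role, "counts_as_major")
  expect_length(minor$groups, 6)
  pr <- proposed_criteria_definition()
  expect_equal(pr$kind, "points")
  expect_equal(vapply(pr$tiers, function(t) length(t$groups), integer(1)),
               c(6L, 3L, 7L))
  expect_equal(vapply(pr$tiers, `[[`, integer(1), "weight"), c(3L, 2L, 1L))
  expect_equal(pr$rule$threshold, 6L)
  expect_equal(pr$family_history_role, "standalone_trigger")
  # every coded id is a well-formed canonical term id
  all_terms <- unlist(lapply(c(ex$tiers, pr$tiers), function(t) {
    lapply(t$groups, `[[`, "terms")
  }))
  expect_identical(unname(all_terms), canonical_term_id(all_terms))
})

test_that("group satisfaction follows the descendant and onset rules", {
  ont <- mini_ontology()
  gu <- term_group(c("HP:0000107", "HP:0000104"), "GU anomaly")
  p <- participant_profile("p1", "HP:0000104", 0L)
  expect_true(group_satisfied(p, gu, ont, at_age_months = 0))
  # unknown onset: counted age-free, excluded at any finite age
  p2 <- participant_profile("p2", "HP:0000104", NA_integer_)
  expect_true(group_satisfied(p2, gu, ont, at_age_months = "any"))
  expect_false(group_satisfied(p2, gu, ont, at_age_months = 60))
  # descendant (relative macrocephaly) satisfies the macrocephaly group
  mac <- term_group("HP:0000256", "Macrocephaly")
  p3 <- participant_profile("p3", "HP:0004482", 12L)
  expect_true(group_satisfied(p3, mac, ont, at_age_months = 12))
  expect_false(group_satisfied(p3, mac, ont, at_age_months = 11))
})

test_that("point scoring sums tier weights, once per group", {
  ont <- mini_ontology()
  # 2 cardinal features (jaw cyst + palmar pits)
  p <- participant_profile("a", c("HP:0010603", "HP:0010610"), c(100L, 90L))
  expect_equal(score_proposed(p, ont), 6L)
  # duplicate matches of one group do not double-count
  dup <- participant_profile("b", c("HP:0000518", "HP:0000519", "HP:0000568"),
                             c(0L, 0L, 0L))
  expect_equal(score_proposed(dup, ont), 3L)
  # scores accumulate with age
  expect_equal(score_proposed(p, ont, at_age_months = 95), 3L)
  expect_equal(score_proposed(p, ont, at_age_months = 100), 6L)
})

test_that("decision rules implement both published variants", {
  ont <- mini_ontology()
  jaw <- "HP:0010603"; pits <- "HP:0010610"           # majors
  mac <- "HP:0000256"; cleft <- "HP:0000175"; poly <- "HP:0010442"  # minors
  mk <- function(terms, fh = FALSE, mol = FALSE) {
    participant_profile("x", terms, rep(0L, length(terms)),
                        family_history = fh, molecular_dx = mol)
  }
  methods <- existing_criteria_definition("methods")
  table2 <- existing_criteria_definition("table2")

  two_maj_one_min <- mk(c(jaw, pits, mac))
  one_maj_three_min <- mk(c(jaw, mac, cleft, poly))
  one_maj_two_min <- mk(c(jaw, mac, cleft))
  expect_true(meets_criteria(two_maj_one_min, methods, ont))
  expect_true(meets_criteria(one_maj_three_min, methods, ont))
  expect_false(meets_criteria(one_maj_two_min, methods, ont))
  expect_true(meets_criteria(one_maj_two_min, table2, ont))
  expect_true(meets_criteria(mk(c(jaw, pits)), table2, ont))
  expect_true(meets_criteria(mk(jaw, mol = TRUE), table2, ont))
  expect_false(meets_criteria(mk(jaw, mol = TRUE), table2, ont,
                              use_molecular = FALSE))

  # family history counts as a major
  fh_one_min <- mk(c(jaw, mac), fh = TRUE)  # 1 coded major + FH + 1 minor
  expect_true(meets_criteria(fh_one_min, methods, ont))
  expect_false(meets_criteria(fh_one_min, methods, ont,
                              use_family_history = FALSE))

  # proposed criteria: family history is a standalone trigger
  pr <- proposed_criteria_definition()
  empty_fh <- mk(character(0), fh = TRUE)
  expect_true(meets_criteria(empty_fh, pr, ont))
  expect_false(meets_criteria(empty_fh, pr, ont, use_family_history = FALSE))
})

test_that("age at first meeting scans correctly", {
  ont <- mini_ontology()
  pr <- proposed_criteria_definition()
  # two cardinal features at 24 and 60 months -> 6 points complete at 60
  p <- participant_profile("a", c("HP:0010603", "HP:0002671"), c(24L, 60L))
  expect_equal(age_first_met(p, pr, ont), 60L)
  # family-history-only profile meets at birth
  fh <- participant_profile("b", family_history = TRUE)
  expect_equal(age_first_met(fh, pr, ont), 0L)
  # never meeting
  never <- participant_profile("c", "HP:0000365", 6L)
  expect_identical(age_first_met(never, pr, ont), NA_integer_)
  # onset past the scan horizon never fires
  late <- participant_profile("d", c("HP:0010603", "HP:0002671"), c(24L, 300L))
  expect_identical(age_first_met(late, pr, ont), NA_integer_)
})

test_that("age_first_met agrees with a brute-force monthly scan", {
  ont <- mini_ontology()
  defs <- list(proposed_criteria_definition(),
               existing_criteria_definition("methods"),
               existing_criteria_definition("table2"))
  cohort <- generate_cohort(default_cohort_config(24L), seed = 515)
  for (defn in defs) {
    for (p in cohort) {
      brute <- NA_integer_
      for (m in 0:216) {
        if (meets_criteria(p, defn, ont, at_age_months = m)) {
          brute <- m
          break
        }
      }
      expect_identical(age_first_met(p, defn, ont), brute)
    }
  }
})

test_that("criteria are monotone and idempotent in the feature list", {
  ont <- mini_ontology()
  pr <- proposed_criteria_definition()
  withr::local_seed(616)
  cohort <- generate_cohort(default_cohort_config(20L), seed = 616)
  extra_pool <- nbccs_target_profile()
  for (p in cohort) {
    base <- score_proposed(p, ont)
    # adding any feature never decreases the score
    extra <- sample(extra_pool, 1)
    grown <- participant_profile(p$id, c(p$features$term, extra),
                                 c(p$features$onset_months, 0L),
                                 p$family_history, p$molecular_dx)
    expect_gte(score_proposed(grown, ont), base)
    # duplicated features leave the score unchanged
    dup <- participant_profile(p$id, rep(p$features$term, 2),
                               rep(p$features$onset_months, 2),
                               p$family_history, p$molecular_dx)
    expect_equal(score_proposed(dup, ont), base)
    # age monotonicity of the decision
    if (!is.na(first <- age_first_met(p, pr, ont))) {
      for (m in unique(c(first, 120, 216))) {
        if (m >= first) expect_true(meets_criteria(p, pr, ont, m))
      }
    }
  }
})

test_that("profile construction validates inputs", {
  expect_error(participant_profile("p", "HP:0000256", -1L), ">= 0")
  expect_error(participant_profile("p", "HP:0000256", c(1L, 2L)), "length")
  p <- participant_profile("p")
  expect_equal(nrow(p$features), 0)
})
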