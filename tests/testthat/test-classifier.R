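test_that("featurize applies descendant closure over the vocabulary", {
  ont <- tiny_ontology()
  A <- "HP:0000002"; B <- "HP:0000003"; C <- "HP:0000004"
  expect_equal(unname(featurize(sim_individual("d", C), c(A, B), ont)),
               c(1L, 0L))
  expect_equal(unname(featurize(sim_individual("d", character(0)), c(A, B), ont)),
               c(0L, 0L))
  # invariant to present-term ordering
  expect_identical(featurize(sim_individual("d", c(A, C)), c(A, B, C), ont),
                   featurize(sim_individual("d", c(C, A)), c(A, B, C), ont))
  expect_error(featurize(sim_individual("d", C), character(0), ont), "nonempty")
})

test_that("training applies Laplace smoothing exactly", {
  ont <- tiny_ontology()
  A <- "HP:0000002"; B <- "HP:0000003"
  cases <- list(sim_individual("c1", A), sim_individual("c2", A))
  controls <- replicate(10, sim_individual("x", B), simplify = FALSE)
  m <- nbc_train(cases, controls, c(A, B), ont, alpha = 1)
  # (2+1)/(2+2) and (0+1)/(10+2), frozen from the smoothing formula
  expect_equal(exp(m$log_p_present["case", A]), 3 / 4, tolerance = 1e-12)
  expect_equal(exp(m$log_p_present["control", A]), 1 / 12, tolerance = 1e-12)
  # per-(class, term) probabilities are complementary and interior
  expect_equal(exp(m$log_p_present) + exp(m$log_p_absent),
               matrix(1, 2, 2, dimnames = dimnames(m$log_p_present)),
               tolerance = 1e-12)
  expect_true(all(exp(m$log_p_present) > 0 & exp(m$log_p_present) < 1))
  expect_equal(sum(exp(m$log_prior)), 1, tolerance = 1e-12)
  # alpha -> 0 limit recovers empirical frequencies
  m0 <- nbc_train(cases, controls, c(A, B), ont, alpha = 1e-12)
  expect_equal(exp(m0$log_p_present["case", A]), 1, tolerance = 1e-9)
  expect_error(nbc_train(list(), controls, c(A, B), ont), "nonempty")
})

test_that("posteriors equal exhaustive Bayes arithmetic on all 2^m vectors", {
  withr::local_seed(55)
  m <- 8
  fl <- flat_ontology(m)
  mk <- function() sim_individual("r", sample(fl$leaves, sample.int(m, 1)))
  cases <- replicate(12, mk(), simplify = FALSE)
  controls <- replicate(20, mk(), simplify = FALSE)
  model <- nbc_train(cases, controls, fl$leaves, fl$ont)
  prior <- exp(model$log_prior)
  p_case <- exp(model$log_p_present["case", ])
  p_ctrl <- exp(model$log_p_present["control", ])
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  for (i in seq_len(nrow(grid))) {
    x <- grid[i, ]
    ind <- sim_individual("v", fl$leaves[x == 1])
    expect_equal(exp(predict_log_posterior(model, ind, fl$ont)),
                 brute_posterior(prior, p_case, p_ctrl, x),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("posterior symmetry, monotone update, and vocabulary permutation", {
  ont <- tiny_ontology()
  A <- "HP:0000002"; B <- "HP:0000003"; C <- "HP:0000004"
  # identical classes + equal sizes -> uniform posterior for any input
  same <- list(sim_individual("a", A), sim_individual("b", B))
  model <- nbc_train(same, same, c(A, B, C), ont)
  post <- predict_log_posterior(model, sim_individual("q", C), ont)
  expect_equal(exp(post), c(case = 0.5, control = 0.5), tolerance = 1e-12)

  # a case-enriched feature strictly increases the case posterior
  cases <- replicate(5, sim_individual("c", A), simplify = FALSE)
  controls <- replicate(5, sim_individual("x", B), simplify = FALSE)
  model2 <- nbc_train(cases, controls, c(A, B), ont)
  without <- predict_log_posterior(model2, sim_individual("q", character(0)), ont)
  with_a <- predict_log_posterior(model2, sim_individual("q", A), ont)
  expect_gt(with_a[["case"]], without[["case"]])

  # shuffling the vocabulary leaves posteriors unchanged
  model3 <- nbc_train(cases, controls, c(B, A), ont)
  expect_equal(predict_log_posterior(model3, sim_individual("q", A), ont),
               predict_log_posterior(model2, sim_individual("q", A), ont),
               tolerance = 1e-12)
})

test_that("cross-validation stratifies, is deterministic, and separates toy data", {
  ont <- tiny_ontology()
  A <- "HP:0000002"; B <- "HP:0000003"
  cases <- replicate(48, sim_individual("c", A), simplify = FALSE)
  controls <- replicate(500, sim_individual("x", B), simplify = FALSE)
  cv <- nbc_cross_validate(cases, controls, c(A, B), ont, folds = 10, seed = 7)
  expect_equal(cv$mean[["accuracy"]], 1.0)  # perfectly separable
  expect_equal(nrow(cv$per_fold), 10)
  cv2 <- nbc_cross_validate(cases, controls, c(A, B), ont, folds = 10, seed = 7)
  expect_identical(cv, cv2)
  expect_error(nbc_cross_validate(cases[1:5], controls, c(A, B), ont,
                                  folds = 10), "at least")
})

test_that("stratified fold sizes differ by at most one within a class", {
  # 48 cases over 10 folds -> sizes 4 or 5 (checked via prediction counts)
  withr::local_seed(77)
  n <- 48; folds <- 10
  sizes <- tabulate(sample(rep_len(seq_len(folds), n)), nbins = folds)
  expect_true(all(sizes %in% c(4L, 5L)))
  expect_equal(sum(sizes), n)
})

test_that("feature ratios rank case-exclusive terms first and are consistent", {
  ont <- tiny_ontology()
  A <- "HP:0000002"; B <- "HP:0000003"; C <- "HP:0000004"
  cases <- replicate(6, sim_individual("c", c(A, B)), simplify = FALSE)
  controls <- replicate(6, sim_individual("x", B), simplify = FALSE)
  model <- nbc_train(cases, controls, c(A, B, C), ont)
  fr <- feature_ratios(model)
  expect_equal(fr$term[1], A)                       # case-exclusive
  expect_equal(fr$log_ratio[fr$term == B], 0)       # equal class frequency
  expect_equal(fr$log_ratio, log(fr$p_case) - log(fr$p_control),
               tolerance = 1e-12)
})

test_that("parameters are recovered from data generated by a known model", {
  withr::local_seed(88)
  m <- 5
  fl <- flat_ontology(m)
  p_case <- c(0.8, 0.6, 0.3, 0.15, 0.5)
  p_ctrl <- c(0.2, 0.5, 0.7, 0.05, 0.5)
  n <- 5000
  gen <- function(p) {
    replicate(n, sim_individual("g", fl$leaves[stats::runif(m) < p]),
              simplify = FALSE)
  }
  model <- nbc_train(gen(p_case), gen(p_ctrl), fl$leaves, fl$ont)
  for (i in seq_len(m)) {
    se <- sqrt(p_case[i] * (1 - p_case[i]) / n)
    expect_lt(abs(exp(model$log_p_present["case", i]) - p_case[i]), 3 * se + 1 / n)
    se <- sqrt(p_ctrl[i] * (1 - p_ctrl[i]) / n)
    expect_lt(abs(exp(model$log_p_present["control", i]) - p_ctrl[i]), 3 * se + 1 / n)
  }
})

test_that("models round-trip through the JSON schema", {
  ont <- tiny_ontology()
  A <- "HP:0000002"; B <- "HP:0000003"
  model <- nbc_train(list(sim_individual("c", A)),
                     list(sim_individual("x", B), sim_individual("y", B)),
                     c(A, B), ont)
  path <- withr::local_tempfile(fileext = ".json")
  write_nbc_model(model, path)
  back <- read_nbc_model(path)
  expect_equal(back$log_p_present, model$log_p_present, tolerance = 1e-12)
  expect_equal(back$log_prior, model$log_prior, tolerance = 1e-12)
  ind <- sim_individual("q", A)
  expect_equal(predict_log_posterior(back, ind, ont),
               predict_log_posterior(model, ind, ont), tolerance = 1e-12)
})
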