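#' Binary feature vector for an individual
#'
#' Element i is 1 when the individual carries `vocabulary[i]` or any of its
#' ontology descendants ([has_feature()]), else 0. Onset ages are ignored:
#' classification uses the age-free feature set.
#'
#' @param ind a `"simulated_individual"` or [participant_profile()].
#' @param vocabulary nonempty character vector of term ids.
#' @param ont an `ontology` (from [parse_obo()]).
#' @return integer vector of 0/1, named by vocabulary term.
#' @export
featurize <- function(ind, vocabulary, ont) {
  if (length(vocabulary) == 0) stop("vocabulary must be nonempty", call. = FALSE)
  vocabulary <- resolve_terms(ont, vocabulary)
  present <- profile_terms(ind)
  if (length(present) == 0) {
    return(stats::setNames(integer(length(vocabulary)), vocabulary))
  }
  hit <- unique(unlist(ont$anc[resolve_terms(ont, present)], use.names = FALSE))
  stats::setNames(as.integer(vocabulary %in% hit), vocabulary)
}

#' Train a Bernoulli naive Bayes classifier
#'
#' Features are descendant-aware term indicators ([featurize()]). Per-class
#' Bernoulli parameters use Laplace smoothing:
#' \eqn{p(t|c) = (n_{present} + \alpha) / (n_c + 2\alpha)}, guaranteeing
#' probabilities strictly inside (0, 1). Class priors are the training class
#' proportions. Everything is stored in log space.
#'
#' @param cases list of case individuals/profiles (nonempty).
#' @param controls list of control individuals/profiles (nonempty).
#' @param vocabulary character vector of term ids.
#' @param ont an `ontology` (from [parse_obo()]).
#' @param alpha smoothing constant > 0 (default 1, Laplace).
#' @return object of class `"nbc_model"`: `vocabulary`, `log_prior` (named
#'   c(case, control)), `log_p_present` / `log_p_absent` (2 x m matrices with
#'   rows case/control), `alpha`, `n_case`, `n_control`.
#' @export
nbc_train <- function(cases, controls, vocabulary, ont, alpha = 1) {
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  stopifnot(alpha > 0)
  vocabulary <- resolve_terms(ont, vocabulary)
  feat <- function(xs) {
    t(vapply(xs, featurize, integer(length(vocabulary)),
             vocabulary = vocabulary, ont = ont))
  }
  x_case <- feat(cases); x_ctrl <- feat(controls)
  n_case <- nrow(x_case); n_ctrl <- nrow(x_ctrl)
  p_case <- (colSums(x_case) + alpha) / (n_case + 2 * alpha)
  p_ctrl <- (colSums(x_ctrl) + alpha) / (n_ctrl + 2 * alpha)
  lp <- rbind(case = log(p_case), control = log(p_ctrl))
  lq <- rbind(case = log1p(-p_case), control = log1p(-p_ctrl))
  colnames(lp) <- colnames(lq) <- vocabulary
  structure(
    list(vocabulary = vocabulary,
         log_prior = log(c(case = n_case, control = n_ctrl) / (n_case + n_ctrl)),
         log_p_present = lp, log_p_absent = lq,
         alpha = alpha, n_case = n_case, n_control = n_ctrl),
    class = "nbc_model"
  )
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("<nbc_model> %d terms, %d cases / %d controls, alpha = %g\n",
              length(x$vocabulary), x$n_case, x$n_control, x$alpha))
  invisible(x)
}

#' Posterior class log-probabilities for an individual
#'
#' Standard naive Bayes update in log space:
#' log prior + sum over features of the matching Bernoulli log-likelihood,
#' normalized (via log-sum-exp) so the exponentials sum to 1.
#'
#' @param model an [nbc_train()] model.
#' @param ind a `"simulated_individual"` or [participant_profile()].
#' @param ont an `ontology` (from [parse_obo()]).
#' @return named numeric `c(case =, control =)` of log posteriors.
#' @export
predict_log_posterior <- function(model, ind, ont) {
  stopifnot(inherits(model, "nbc_model"))
  x <- featurize(ind, model$vocabulary, ont)
  joint <- model$log_prior +
    as.vector(model$log_p_present %*% x + model$log_p_absent %*% (1L - x))
  m <- max(joint)
  joint - (m + log(sum(exp(joint - m))))
}

classify <- function(model, ind, ont) {
  lp <- predict_log_posterior(model, ind, ont)
  # tie -> control: deterministic and conservative for a screening tool
  if (lp[["case"]] > lp[["control"]]) "case" else "control"
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Folds are stratified per class (fold sizes differ by at most one member
#' within a class); every record is tested exactly once. Assignment is
#' seed-deterministic.
#'
#' @inheritParams nbc_train
#' @param folds number of folds (default 10); each class must have at least
#'   this many members.
#' @param seed optional integer seed for the fold assignment.
#' @return list with `per_fold` (data.frame: fold, accuracy, sensitivity,
#'   specificity) and `mean` (named numeric of column means).
#' @export
nbc_cross_validate <- function(cases, controls, vocabulary, ont,
                               folds = 10L, alpha = 1, seed = NULL) {
  if (length(cases) < folds || length(controls) < folds) {
    stop("each class needs at least `folds` members", call. = FALSE)
  }
  assign_folds <- function(n) sample(rep_len(seq_len(folds), n))
  fold_of <- function() list(case = assign_folds(length(cases)),
                             control = assign_folds(length(controls)))
  fo <- if (is.null(seed)) fold_of() else withr::with_seed(seed, fold_of())
  per_fold <- data.frame(fold = seq_len(folds), accuracy = NA_real_,
                         sensitivity = NA_real_, specificity = NA_real_)
  for (f in seq_len(folds)) {
    tr_cases <- cases[fo$case != f]; te_cases <- cases[fo$case == f]
    tr_ctrl <- controls[fo$control != f]; te_ctrl <- controls[fo$control == f]
    model <- nbc_train(tr_cases, tr_ctrl, vocabulary, ont, alpha = alpha)
    pred_case <- vapply(te_cases, classify, character(1), model = model, ont = ont)
    pred_ctrl <- vapply(te_ctrl, classify, character(1), model = model, ont = ont)
    tp <- sum(pred_case == "case"); fn <- length(pred_case) - tp
    tn <- sum(pred_ctrl == "control"); fp <- length(pred_ctrl) - tn
    per_fold$accuracy[f] <- (tp + tn) / (tp + fn + tn + fp)
    per_fold$sensitivity[f] <- tp / (tp + fn)
    per_fold$specificity[f] <- tn / (tn + fp)
  }
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("accuracy", "sensitivity", "specificity")]))
}

#' Per-term class probability ratios
#'
#' One row per vocabulary term with the smoothed presence probabilities in
#' each class and their log ratio \eqn{\ln p(t|case) - \ln p(t|control)};
#' sorted by descending log ratio, ties broken by term id. These ratios are
#' the model output used to inform which features belong in a revised
#' criteria tier.
#'
#' @param model an [nbc_train()] model.
#' @return data.frame: `term`, `p_case`, `p_control`, `log_ratio`.
#' @export
feature_ratios <- function(model) {
  stopifnot(inherits(model, "nbc_model"))
  p_case <- exp(model$log_p_present["case", ])
  p_ctrl <- exp(model$log_p_present["control", ])
  df <- data.frame(term = model$vocabulary, p_case = unname(p_case),
                   p_control = unname(p_ctrl),
                   log_ratio = unname(log(p_case) - log(p_ctrl)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$log_ratio, df$term), ]
  rownames(df) <- NULL
  df
}

#' Serialize / restore an NBC model as JSON
#'
#' The schema is flat and documented: `vocabulary`, `prior` (probabilities),
#' `p_present` per class, `alpha`, class sizes.
#'
#' @param model an [nbc_train()] model.
#' @param path file path.
#' @return `path` (writer) / an `"nbc_model"` (reader).
#' @export
write_nbc_model <- function(model, path) {
  stopifnot(inherits(model, "nbc_model"))
  obj <- list(
    vocabulary = model$vocabulary,
    prior = as.list(exp(model$log_prior)),
    p_present = list(case = unname(exp(model$log_p_present["case", ])),
                     control = unname(exp(model$log_p_present["control", ]))),
    alpha = model$alpha, n_case = model$n_case, n_control = model$n_control
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nbc_model
#' @export
read_nbc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p_case <- obj$p_present$case; p_ctrl <- obj$p_present$control
  lp <- rbind(case = log(p_case), control = log(p_ctrl))
  lq <- rbind(case = log1p(-p_case), control = log1p(-p_ctrl))
  colnames(lp) <- colnames(lq) <- obj$vocabulary
  structure(
    list(vocabulary = obj$vocabulary,
         log_prior = log(c(case = obj$prior$case, control = obj$prior$control)),
         log_p_present = lp, log_p_absent = lq,
         alpha = obj$alpha, n_case = obj$n_case, n_control = obj$n_control),
    class = "nbc_model"
  )
}

#' Default classifier vocabulary
#'
#' The union of all term groups appearing in either criteria definition —
#' the features over which the criteria themselves are defined. Pass any
#' other term set (e.g. all terms annotated to the control diseases) to the
#' training functions for a wider model.
#'
#' @return character vector of canonical term ids.
#' @export
default_vocabulary <- function() nbccs_target_profile()
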