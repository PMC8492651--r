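# Shared fixtures and independent brute-force oracles. The oracles use only
# naive set expansion / explicit probability arithmetic so they stay
# independent of the package's closure- and log-space-based implementations.

write_obo_fixture <- function(stanzas) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}

# 4-term fixture: root R; A, B is_a R; C is_a A.
# R = HP:0000001, A = HP:0000002, B = HP:0000003, C = HP:0000004
tiny_ontology <- function() {
  path <- write_obo_fixture(c(
    "[Term]", "id: HP:0000001", "name: root", "",
    "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000004", "name: C", "is_a: HP:0000002", ""
  ))
  parse_obo(path)
}

# Companion annotations: D1 {C}; D2 {A, B}; D3 {B}.
tiny_annotations <- function(ont) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("disease_id\thpo_id",
               "D1\tHP:0000004",
               "D2\tHP:0000002", "D2\tHP:0000003",
               "D3\tHP:0000003"), path)
  read_annotations(path, ont)
}

mini_ontology <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- parse_obo(system.file("extdata", "mini_hp.obo",
                                      package = "gorlin"))
    }
    cache
  }
})

mini_annotation_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- read_annotations(
        system.file("extdata", "mini_annotations.tsv", package = "gorlin"),
        mini_ontology())
    }
    cache
  }
})

# Random DAG: term i (i > 1) picks 1-2 parents among terms 1..(i-1), so the
# graph is acyclic by construction. Term 1 is the root.
random_ontology <- function(n_terms, max_parents = 2L) {
  ids <- sprintf("HP:%07d", seq_len(n_terms))
  stanzas <- c("[Term]", paste0("id: ", ids[1]), "name: root", "")
  for (i in 2:n_terms) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents <- sample(ids[seq_len(i - 1L)], k)
    stanzas <- c(stanzas, "[Term]", paste0("id: ", ids[i]),
                 paste0("name: t", i), paste0("is_a: ", parents), "")
  }
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", stanzas), path)
  parse_obo(path)
}

random_annotations <- function(ont, n_diseases, max_terms = 4L) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  rows <- "disease_id\thpo_id"
  for (d in seq_len(n_diseases)) {
    terms <- sample(ont$terms, sample.int(max_terms, 1L))
    rows <- c(rows, paste0(sprintf("D%03d", d), "\t", terms))
  }
  writeLines(rows, path)
  read_annotations(path, ont)
}

# --- brute-force oracles ---------------------------------------------------

# Reflexive closure by repeated one-step edge expansion until fixpoint.
brute_closure <- function(edges, term) {
  out <- term
  repeat {
    grown <- unique(c(out, unlist(edges[out], use.names = FALSE)))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}
brute_ancestors <- function(ont, term) brute_closure(ont$parents, term)
brute_descendants <- function(ont, term) brute_closure(ont$children, term)

# IC from explicitly propagated per-disease counts.
brute_ic <- function(annotations, ont) {
  n <- length(annotations)
  ic <- numeric(0)
  for (t in ont$terms) {
    desc <- brute_descendants(ont, t)
    count <- sum(vapply(annotations,
                        function(terms) length(intersect(terms, desc)) > 0,
                        logical(1)))
    if (count > 0) ic[[t]] <- -log(count / n)
  }
  ic
}

brute_resnik <- function(t1, t2, ont, ic) {
  common <- intersect(brute_ancestors(ont, t1), brute_ancestors(ont, t2))
  vals <- ic[intersect(common, names(ic))]
  if (length(vals) == 0) 0 else max(0, max(vals))
}

brute_bma <- function(p1, p2, ont, ic) {
  best <- function(a, b) {
    mean(vapply(a, function(t) {
      max(vapply(b, function(u) brute_resnik(t, u, ont, ic), numeric(1)))
    }, numeric(1)))
  }
  (best(p1, p2) + best(p2, p1)) / 2
}

# Explicit Bayes-rule arithmetic on the joint probability of a 0/1 vector,
# computed in plain (non-log) space.
brute_posterior <- function(prior, p_case, p_ctrl, x) {
  joint_case <- prior[["case"]] * prod(ifelse(x == 1, p_case, 1 - p_case))
  joint_ctrl <- prior[["control"]] * prod(ifelse(x == 1, p_ctrl, 1 - p_ctrl))
  c(case = joint_case, control = joint_ctrl) / (joint_case + joint_ctrl)
}

sim_individual <- function(disease_id, terms) {
  structure(list(disease_id = disease_id, present_terms = sort(terms)),
            class = "simulated_individual")
}

# Ontology of m independent leaves under one root: any 0/1 feature vector
# over the leaves is realizable by a term set.
flat_ontology <- function(m) {
  ids <- sprintf("HP:%07d", 1L + seq_len(m))
  stanzas <- c("[Term]", "id: HP:0000001", "name: root", "")
  for (i in seq_len(m)) {
    stanzas <- c(stanzas, "[Term]", paste0("id: ", ids[i]),
                 paste0("name: leaf", i), "is_a: HP:0000001", "")
  }
  path <- write_obo_fixture(stanzas)
  list(ont = parse_obo(path), leaves = ids)
}
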