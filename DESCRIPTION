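Package: gorlin
Title: Pediatric Diagnostic Criteria Evaluation for Nevoid Basal Cell
    Carcinoma Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and quantitative evaluation of pediatric
    diagnostic criteria for nevoid basal cell carcinoma syndrome (NBCCS,
    Gorlin syndrome) using the Human Phenotype Ontology (HPO). Provides an
    OBO ontology parser with ancestor/descendant closure queries,
    annotation-based information content and Resnik semantic similarity,
    Monte Carlo simulation of control patients from disease-to-phenotype
    annotation tables, a Bernoulli naive Bayes classifier over
    descendant-aware binary phenotype features, machine encodings of the
    existing major/minor criteria and a proposed point-based scheme, a
    calibrated synthetic survey-cohort generator, and age-resolved
    sensitivity plus Monte Carlo specificity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
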