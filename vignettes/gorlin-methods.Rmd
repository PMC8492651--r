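---
title: "Methods: quantitative evaluation of pediatric NBCCS diagnostic criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative evaluation of pediatric NBCCS diagnostic criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gorlin)
```

## The problem

Nevoid basal cell carcinoma syndrome (NBCCS, Gorlin syndrome) is an
autosomal dominant tumor-predisposition syndrome (PTCH1/SUFU). Its
consensus diagnostic criteria lean on features — widespread basal cell
carcinomas, jaw keratocysts, falx calcification — that typically emerge in
adolescence or adulthood, so affected children are diagnosed late even
though most have recognizable congenital or early-childhood findings.
`gorlin` implements the machinery for asking, quantitatively, how a
diagnostic criteria set performs in children: how sensitivity accrues with
age in an affected cohort, and how specific the criteria are against
patients with *other* genetic disorders.

Everything is phrased over the Human Phenotype Ontology (HPO): clinical
features are HP terms, and a criterion term is satisfied by any profile
term equal to it or below it in the `is_a` hierarchy (descendant matching,
with reflexive closure so an exact hit always counts).

## Components and their models

### Ontology, annotations, information content

`parse_obo()` builds a DAG from `is_a` edges only; `part_of` and other
relations are ignored (HPO is `is_a`-dominant). Obsolete stanzas are
dropped; `alt_id`s are resolved to canonical ids at every ingestion
boundary so internal code only ever sees canonical terms. Information
content is the standard annotation-frequency form: with `D` diseases and
`d(t)` the number annotated to term `t` or any descendant,

$$IC(t) = -\ln\left(d(t) / D\right)$$

in nats (natural log, Resnik's original convention; the base does not
affect which common ancestor is maximal). Terms with no propagated
annotation get *no* IC entry rather than infinite IC, and similarity
queries treat missing IC as 0 — this avoids ±Inf propagation and means an
unannotated ancestor can never dominate a MICA search.

### Resnik similarity and disease ranking

Term similarity is the IC of the most informative common ancestor.
Profile similarity defaults to the symmetric best-match average (BMA): the
paper trail for this analysis names only "Resnik similarity" through an
ontology-similarity package whose aggregation is not quoted, and BMA is the
dominant convention, symmetric and deterministic; `max` and
`mean-pairwise` are provided as options. The query profile used to rank
diseases against NBCCS defaults to the union of every HP term named in
either criteria encoding (`nbccs_target_profile()`), and ranking ties are
broken by ascending disease id so a top-k set is exactly reproducible.
Because the aggregation and target profile used in the original analysis
are not recoverable, a top-500 set computed here on real HPO/OMIM data is
*comparable* to the published one, not identical.

### Simulated controls

A simulated control patient of disease `d` with `K` annotated terms draws a
feature count `k ~ Uniform{1, ..., K}`, then `k` distinct terms uniformly
without replacement. Uniform-on-count is the plainest reading of "a random
number of features among all annotated features"; it implies a per-term
inclusion probability of `(K+1)/(2K)`, which the tests verify. Diseases
are drawn uniformly from the chosen subset (no prevalence weighting — the
source analysis states none). Simulated controls carry no onset ages:
OMIM annotations lack onset, so specificity is evaluated age-free
("at adulthood"), with family history and molecular diagnosis off.

### Bernoulli naive Bayes

Features are descendant-aware binary indicators over a vocabulary
(default: the criteria terms). Training uses Laplace smoothing
`p(t|c) = (n_present + α)/(n_c + 2α)` with `α = 1` (the conventional
default of the fast NB implementations this mirrors; configurable), class
priors are training proportions, and all arithmetic is in log space with
log-sum-exp normalization. Prediction ties go to "control" —
deterministic, and conservative for a screening context.
Cross-validation is stratified per class with seed-fixed assignment; the
suite checks posteriors against exhaustive joint-probability Bayes
arithmetic on every vector of a 10-feature space.

The classifier informs criteria design (via `feature_ratios()`); it is not
itself the diagnostic instrument. How the original authors thresholded
ratios into tiers is not stated, so tier membership here is encoded
verbatim from the published tables rather than re-derived.

### Criteria encodings

Two definitions ship:

* **Existing (major/minor).** Four coded major groups (jaw keratocysts,
  palmoplantar pits, falx calcification, basal cell carcinoma) plus an
  affected first-degree relative acting as a fifth major; six minor
  groups. The literature states two conflicting decision rules, and both
  are implemented: the default `"methods"` variant (2 majors + 1 minor, or
  1 major + 3 minors) and the `"table2"` variant (1 major + molecular
  diagnosis, 2 majors, or 1 major + 2 minors). Which one the original
  age-resolved analysis used is inferred, not stated — hence the switch.
* **Proposed (points).** Cardinal features score 3, suggestive 2, possible
  1; molecular testing is suggested at ≥ 6 points, and an affected
  first-degree relative triggers the recommendation on its own. Each group
  contributes its weight once regardless of how many profile features
  match it. Parenthesized clinical qualifiers of the published table
  (centile cutoffs, SHH-subtype medulloblastoma) are advisory and not
  encoded; ovarian/cardiac fibroma and lymphomesenteric cysts are omitted
  from the machine definitions (never reported in the calibration cohort
  and absent from the coded term lists). The punctuation-ambiguous
  polydactyly code (HP:0010442) is treated as its own minor group.

Age semantics: onset 0 encodes congenital/prenatal findings; an unknown
onset counts in age-free evaluation but never at a finite age; family
history, when used, is assumed known at birth (month 0). Because features
only accumulate, criteria decisions are monotone in age —
`age_first_met()` exploits this by scanning only candidate onset ages, and
the suite cross-checks it against a brute-force scan of all 217 monthly
points.

## The synthetic cohort: what it is and is not

The 48-participant survey behind the published analysis is not deposited,
so `default_cohort_config()` states a synthetic world calibrated to the
published per-feature marginals: prevalences (e.g. jaw keratocysts 0.69,
rib anomalies 0.42, fibromas 0.00) and median onsets (jaw keratocysts
120 months, palmar/plantar pitting 89, BCC 170, falx calcification 174,
medulloblastoma 10, macrocephaly 1; ocular, cleft, rib and skeletal
findings congenital at 0). Family history has probability 0.25
(12/48 with affected first-degree relatives) and molecular diagnosis 0.40
(19/48 with a PTCH1 or SUFU variant — a value the calibration table does
not give, taken from the demographics table). Where the source reports a
conflict (macrocephaly 58% at 1 month in the criteria table vs 62%
"congenital" in the prose), the criteria table is followed.

Non-congenital onsets are lognormal with the published median
(`meanlog = log(median)`) and `sdlog = 0.6`, rounded to months and clamped
to [0, 216]; the published onset-range figure is not machine-readable, so
the spread is a fixed, documented choice rather than a fitted one
(clamping at the tail does not move the median, which is the calibrated
quantity). Features are sampled *independently*: only marginals were
published, so joint structure is absent by construction.

Consequently a green test establishes that the machinery — parsing,
closure, scoring, curves, Monte Carlo counts — is correct and that the
generator reproduces its stated marginals. It does **not** reproduce the
cohort-specific survey figures (50% sensitivity at 1 year, 60% at 7 years,
83% at adulthood, the 8-month/7-year/16.8-year/6-year/5-month medians) or
the 86.7% specificity, which additionally depends on an unstated HPO/OMIM
release and similarity aggregation. The pipeline exposes a full-scale mode
(real `hp.obo` + `phenotype.hpoa`, `n = 50,000`, `k = 500`) for qualitative
comparison with that figure.

## Numerical and convention choices

* IC and similarity in nats; missing IC ≡ 0.
* Lower median for even cohort sizes in `median_age_at_criteria()`; a
  cohort where more than half never meet the criteria has median `NA`.
* Classifier ties predict "control".
* Ranking and ratio ties break by ascending id.
* All stochastic stages take explicit seeds (`withr::with_seed`, caller RNG
  untouched); identical seeds give bit-identical cohorts, folds and
  reports.
* Degenerate inputs fail fast: empty profiles/classes/cohorts/tables are
  argument errors, unknown terms are lookup errors after alt-id
  resolution, malformed OBO stanzas report their line, and cycles abort
  parsing.

## Known limitations

* The shipped miniature ontology is a synthetic stand-in: real HP ids with
  plausible labels and placements, sufficient for the criteria logic but
  not a subset of any HPO release.
* Independent feature sampling understates within-patient correlation, so
  cohort-level sensitivities computed on synthetic data are machinery
  checks, not clinical estimates.
* Only `is_a` edges are used; no OWL input; no Lin/JC/Wang similarity; no
  frequency-modifier-aware control sampling.
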