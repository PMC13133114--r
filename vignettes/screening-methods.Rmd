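---
title: "Screening cohort features for novel, plausible, useful hypotheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cohort features for novel, plausible, useful hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novelfeat)
```

## The problem

Given a patient-level feature table with a binary disease outcome, most
feature-selection workflows stop at predictive importance: rank features by a
model attribution or a p-value and read the top of the list. But the top of
that list is dominated by associations everyone already knows. The scientific
question is usually the opposite one — *which predictive features are not yet
established as risk factors?*

`novelfeat` operationalizes this as a filtering cascade over candidate
hypotheses of the form "feature *x* is related to target *y*, with a
positive/negative correlation":

1. **Utility** — does *x* carry predictive signal for *y* at all?
2. **Knowledge-graph novelty** — is the *x*–*y* link already recorded in a
   citation-backed knowledge base?
3. **Literature novelty** — are *x* and *y* already co-mentioned in the
   literature more than chance would predict?
4. **Annotation** — a language-model provider scores the survivors 1–4 for
   novelty, plausibility and overall interestingness, with rationales, and
   the top of that ranking goes to expert review.

A hypothesis is *interesting* when it is simultaneously novel, plausible and
useful; the cascade is a sequence of cheap, high-recall screens that discard
only clear failures of one criterion at a time.

## Cohort preparation

`prep_cohort()` applies, in order: removal of features with fewer than 30
observed values; mean imputation with a companion `<name>__missing` indicator
for every feature that actually had gaps (features without gaps get no flag,
so no constant columns appear); greedy correlation deduplication at
|r| > 0.9 in declared column order (the first-seen feature of a redundant
pair is kept — a deterministic, auditable rule); and optional
propensity-weighted downsampling of controls.

The downsampling step fits a logistic propensity model
P(y = 1 | age, sex, BMI) and samples controls without replacement with
probability proportional to their predicted propensity, down to a 9:1
control:case ratio. Controls that resemble the cases in the baseline
covariates are preferentially retained, which empirically pulls the control
covariate means toward the case means and reduces the degree to which
age/sex/BMI confounding leaks into downstream feature scores. The order of
the prep steps matters — imputation needs observed means, the correlation
screen needs complete columns — and the full pass is idempotent.

## The utility screen

Three per-feature criteria, combined as a disjunction by default:

* `univariate_pvalue()` — Welch's two-sample t-test between outcome classes
  for continuous features; a chi-square test of independence for features
  with at most 5 distinct values, switching to Fisher's exact test when any
  expected cell is below 5. The pass rule is strict: p < θ_p.
* `mutual_information()` — plug-in MI in nats over a joint table after
  quantile-binning continuous features into (by default) 10 bins. The
  plug-in estimator is biased upward at small n, but it is reproducible,
  cheap, and exactly checkable against the direct entropy sum; the screen
  uses it only against a permissive threshold, not as an effect estimate.
* `model_importance()` — a gradient-boosted tree classifier (xgboost,
  logistic objective, depth 4, η = 0.3, 50 rounds) trained under 3-fold
  cross-validation; each feature's importance is the global mean absolute
  per-sample additive attribution (TreeSHAP) on held-out folds. Attributions
  plus the bias term reproduce the model margin to float32 precision, which
  the tests verify.

Defaults are θ_p = 0.2, θ_MI = 10⁻³, θ_FImp = 10⁻⁴ with `mode = "any"`.
These are deliberately lenient: the utility stage exists to discard features
with *no* signal, not to build a calibrated risk model, and downstream
novelty filters do the real pruning. `threshold_sensitivity()` reports how a
reference feature set's recall decays as θ_p tightens (0.2 → 0.01 → 0.001);
recall is provably non-increasing in stringency, and lowering any threshold
can only grow the pass set.

The exact univariate test, MI estimator and booster settings are design
choices of this package: with thresholds this permissive the pass set is
insensitive to reasonable substitutions, and each choice was made for
testability (closed-form or oracle-checkable behaviour) over novelty.

## Concept linking

Feature names are free text; the knowledge graph speaks entity ids. A
pluggable provider maps text to candidate entities (`link(text)`) and embeds
text for similarity (`embed(text)`). At most 3 entities are kept per feature,
each with linker confidence ≥ 0.88 — a high-precision operating point —
with confidence ties broken by entity id so truncation is stable.
Uninformative high-level categories (e.g. "Qualification", "Unit") are
removed by case-insensitive regex. Cosine similarity between the feature
text and each entity's canonical name then removes barely-related entities
(sim < 0.1) and flags *strongly linked* ones (sim ≥ 0.4, boundary
inclusive); similarity is computed against the canonical name rather than
the matched span, a choice we make explicit because either reading is
defensible. Category exclusion and the similarity gate are both row filters,
so they commute — the tests check this.

The bundled provider is deterministic and offline: token-overlap (Jaccard)
scoring against an entity lexicon for linking, and hashed character-trigram
vectors for embedding. It is not a biomedical entity linker — it has no
abbreviation handling, no synonymy beyond token overlap — but it is exact,
reproducible byte-for-byte, and sufficient for a lexicon whose names are
controlled. Real linkers/embedders plug in through the same two-function
interface.

## Knowledge-graph novelty

`load_kg()` reads subject–predicate–object triples, ignores predicate type
and direction (the graph is treated as undirected adjacency), drops edges
with fewer than 2 unique supporting citations, and merges parallel edges
keeping the maximum evidence count and earliest first-report year. A feature
is marked **known** when either every linked entity is 1-hop adjacent to a
target entity, or at least one strongly linked entity is. Unlinked features
are treated as novel by default: the screen prioritizes precision in
exclusion, and a feature the linker cannot place should not be silently
discarded. `is_known()` is verified against a brute-force evaluation of
this boolean rule on every link configuration of size ≤ 3 over a toy graph,
and adding edges can only move verdicts from novel to known, never back.

Each edge's `first_year` makes temporal validation possible:
`temporal_split()` partitions the graph at a cutoff year, and
`temporal_validation()` reports, among utility-filtered features, how many
are KG-linked, how many are 1-hop from the target, and what share of those
first acquired their target edge *after* the cutoff — with a 95% Wilson
score interval on that share (denominator: the 1-hop count). A feature whose
association entered the knowledge base only after the data era is evidence
the screen surfaces associations ahead of their recognition. The toy triple
format carries `first_year` as an explicit column; deriving first-report
years from raw citation records is out of scope.

## Literature novelty

For each surviving pair the provider returns hit counts n_x, n_y, the
co-mention count n_xy, and the corpus size N (default 37 million documents,
configurable). The pair is retained as not-yet-established when any of:

* the feature term is rare (n_x < 20 hits — recently coined terms should not
  be filtered on the basis of absence);
* co-mentions are few in absolute terms (n_xy < θ_lit = 4);
* co-occurrence is *under-represented*: the lower hypergeometric tail
  P(X ≤ n_xy) for X ~ Hypergeometric(N, n_x, n_y) — equivalently a one-way
  Fisher exact test with alternative "less" on the 2×2 document table — is
  below θ_pval = 0.4.

The document-universe hypergeometric is the canonical reading of a one-way
exact test on co-occurrence counts; the implementation is checked against
full table enumeration for small corpora. Retention is monotone: at fixed
margins, once a pair is filtered at some n_xy it stays filtered for all
larger n_xy, and tightening either threshold only shrinks the retained set
(the rare-feature bypass is threshold-independent by design).

## Annotation and selection

Candidates reaching the final stage are scored by a provider exposing a
single `complete(prompt)` function. Prompts are chain-of-thought templates
with slots for the feature, target, effect direction, utility statistics and
optional retrieved context, and demand a machine-parseable answer block;
`parse_annotation()` validates the three 1–4 scores and surfaces malformed
output as a typed condition, retried twice before the candidate is flagged
unannotated. Retrieval uses Okapi BM25 (k1 = 1.5, b = 0.75) over a supplied
corpus, top 32 documents per candidate, with deterministic tie-breaking.

Scores are binarized at > 2 when compared against expert annotations.
`select_candidates()` keeps interestingness > 2, ranks by confidence
descending — the confidence key is the overall interestingness score itself;
the two are equated here, with the ranking key exposed as a column so a
different confidence signal can be substituted — breaking ties by model
importance then feature id, and truncates to the top 30 for review.

Only the scripted deterministic provider ships with the package: it replays
a score map keyed by candidate id, which makes the entire stage offline and
reproducible and lets tests exercise the parser's failure paths. Any hosted
model can be adapted by wrapping its API in `complete(prompt)`.

## Evaluation machinery

The package implements the metrics needed to evaluate a screen end to end:
Wilson score intervals (`wilson_ci`), exact two-sided Fisher tests
(`fisher_two_sided`, checked against table enumeration), unweighted Cohen's
kappa on raw 1–4 scores, binarized agreement, Welch two-sample t-tests,
NDCG with *linear* gain in the 1–4 rating (the conservative reading of
"graded relevance"; an exponential gain would be a config-level change), MRR
with relevance defined as rating ≥ 3, and `inject_distractors()`, which
mixes ceiling(20%) utility-rejected features into an annotation set under a
hidden label map to measure annotator discrimination. Reported percentages
and interval bounds round to the nearest integer percent.

## Synthetic study conditions

`generate_world()` builds every input the cascade needs, with ground truth:

* **Cohort** — baseline covariates age ~ N(57, 8), sex ~ Bernoulli(0.5),
  BMI ~ N(27, 4), matching a mid-life population cohort; independent
  standard-normal null features; planted features with stated log-odds-per-SD
  effects; outcome drawn from the logistic model with the intercept
  calibrated numerically to the requested prevalence; missingness injected
  completely at random. MCAR is the weakest assumption the prep stage's
  mean-impute-and-flag contract can be tested under; informative missingness
  is deliberately not emulated.
* **Knowledge graph** — one entity per planted feature plus the target and
  a few background concepts; every `kg_known` feature gets a 3-citation edge
  to the target (first reported 2005 by default); random background edges.
* **Literature counts** — every `lit_known` feature is given 1000 hits and
  500 co-mentions with the target against N = 37 million, which the
  under-representation test correctly refuses to call novel; all other
  features fall under the rare-term bypass.
* **Annotation** — a scripted provider that scores every candidate (3, 3, 3)
  by default, so final ranking is carried by the importance tie-break.

Confounders enter the outcome model linearly through standardized
covariates; this is the minimal structure under which propensity
downsampling demonstrably changes feature ranking. What passing tests on
this world show is that the *machinery* is correct — each stage excludes
exactly what its rule says — not that the screen would behave identically
on real cohort data, where features are correlated, missingness is
informative, linkers are noisy and knowledge bases are incomplete.

The test suite and the bundled acceptance script use cohorts of
n = 2000–5000 with 50–63 features and ten replicate seeds for the
end-to-end recovery check — sizes chosen so the planted effect (≥ 1 log-odds
per SD) is unambiguous and the whole suite runs in well under a minute on a
laptop. On a panel of one planted novel feature, twelve planted known
associations and fifty nulls, the planted novel feature reaches the final
selection and every planted known feature is removed by the KG or literature
stage in 10/10 seeds.

## Numerical and degenerate-input conventions

Constant features: p = 1 with a warning (no information), excluded from the
correlation screen but retained, an error in `effect_direction()`.
Zero-norm embeddings: similarity 0 with a warning. Wilson bounds are snapped
exactly to 0 (k = 0) and 1 (k = n) where cancellation would otherwise leave
10⁻¹⁷-scale noise. Empty link sets: novel-by-default. Empty candidate sets
at any stage: valid empty outputs, never an error. All tie-breaks
(link truncation, BM25, selection) are deterministic. Every stochastic step
(cohort draw, background edges, fold assignment, downsampling, distractor
injection) takes an explicit seed, and a screen re-run with the same config
and seed is reproducible component-for-component.

## Limitations

The bundled linker is lexical; real deployments should plug in a biomedical
entity linker and sentence embedder. The knowledge-graph and literature
screens inherit the coverage biases of their sources — a thin knowledge base
inflates apparent novelty. The plug-in MI estimate and the boosted-model
importances are screening statistics, not effect sizes. Feature interactions
and non-monotone effects are outside the hypothesis space, which is
restricted to signed univariate associations.
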