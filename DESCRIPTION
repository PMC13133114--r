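Package: novelfeat
Title: Screening Cohort Features for Novel, Plausible, Useful Hypotheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A filtering cascade for discovering candidate risk-factor
    hypotheses in patient-level cohort data. Features are scored for
    predictive utility (univariate tests, mutual information, gradient
    boosted model attributions), screened for novelty against a
    citation-filtered knowledge graph of biomedical entities and against
    literature co-mention counts (one-sided hypergeometric
    under-representation test), then annotated and ranked for novelty,
    plausibility and overall interestingness through a pluggable language
    model provider with optional BM25-retrieved context. Includes synthetic
    cohort, knowledge-graph and literature generators with planted ground
    truth, and the evaluation machinery for temporal validation (Wilson
    score intervals), baseline comparison (two-sided Fisher exact tests),
    distractor injection, inter-rater agreement (Cohen's kappa) and ranking
    quality (NDCG, MRR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xgboost
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
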