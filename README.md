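# novelfeat

Screening cohort features for **novel, plausible, useful** risk-factor
hypotheses.

## What problem this solves

Epidemiologists and data scientists working with large patient-level cohorts
(hundreds to thousands of mixed numeric/binary features, a binary disease
outcome, baseline covariates such as age, sex and BMI) routinely rank
features by predictive importance and read the top of the list. The top of
that list is dominated by associations that are already textbook knowledge.
`novelfeat` inverts the question: among the features that *do* carry
predictive signal, which ones are **not yet established** as risk factors —
and of those, which are plausible enough to be worth an expert's time?

The package implements a staged filtering cascade over candidate hypotheses
"feature *x* is related to target *y*, with a positive/negative correlation":

1. **Utility filter.** A feature passes (by default) if *any* of:
   univariate p-value p(x, y) < θ_p (Welch t-test for continuous features,
   chi-square/Fisher for discrete); mutual information MI(x, y) ≥ θ_MI
   (plug-in estimate over quantile bins, in nats); or model importance
   FImp(x, y) ≥ θ_FImp (global mean |per-sample TreeSHAP attribution| from a
   cross-validated gradient-boosted classifier). Defaults θ_p = 0.2,
   θ_MI = 10⁻³, θ_FImp = 10⁻⁴ — deliberately lenient.
2. **Knowledge-graph novelty.** Feature text is linked to at most 3 entities
   (linker confidence ≥ 0.88), gated by category regexes and cosine
   similarity (drop sim < 0.1; "strongly linked" at sim ≥ 0.4). In a
   citation-filtered undirected knowledge graph (edges need ≥ 2 unique
   citations), a feature is *known* — and excluded — iff all its linked
   entities are 1-hop adjacent to a target entity, or any strongly linked
   entity is.
3. **Literature novelty.** With hit counts n_x, n_y, co-mentions n_xy in a
   corpus of N documents, a pair is retained iff n_x < 20 (rare term), or
   n_xy < θ_lit = 4, or the one-sided under-representation tail
   P(X ≤ n_xy), X ~ Hypergeometric(N, n_x, n_y), is below θ_pval = 0.4.
4. **Annotation and ranking.** A pluggable language-model provider scores
   survivors 1–4 for novelty, plausibility and overall interestingness
   (chain-of-thought prompts, optional BM25-retrieved context, structured
   parsing with retries); candidates with interestingness > 2 are ranked and
   truncated to the top 30 for expert review.

Evaluation machinery is included: Wilson score intervals, exact two-sided
Fisher tests, Cohen's kappa, binarized agreement, Welch t-tests, NDCG/MRR,
distractor injection, and temporal validation (which share of surfaced
feature–target links first entered the knowledge base only *after* a
historical cutoff). Synthetic generators build every input — cohort with
planted effects, toy knowledge graph, literature counts, scripted annotator
— so the whole cascade runs and is tested fully offline.

## Worked example

```r
library(novelfeat)

planted <- data.frame(
  feature   = c("serum_urate", "alcohol_intake", "shoe_size_marker"),
  effect    = c(1.2, 1.0, 1.0),          # log-odds per SD
  kg_known  = c(FALSE, TRUE,  FALSE),    # already in the knowledge graph
  lit_known = c(FALSE, FALSE, TRUE))     # already heavily co-mentioned

spec <- synthetic_spec(2000, 30, 0.1, planted, missing_rate = 0.05, seed = 11)
w <- generate_world(spec)                # cohort + KG + counts + annotator

scr <- feature_screen(w$cohort, w$target_name, w$target_entities, w$kg,
                      w$link_provider, w$lit_provider, w$llm_provider,
                      w$corpus, config = screen_config(seed = 11))
print(scr)
```

```
Feature screen for "gout"
Funnel (features surviving each stage):
  prepared   66
  utility    47
  kg         46
  literature 45
  selected   30
Top candidates:
   1. serum urate (positive, interestingness 3)
   2. feat 015 (negative, interestingness 3)
   3. feat 024 (negative, interestingness 3)
   4. feat 013 (positive, interestingness 3)
   5. feat 007 (positive, interestingness 3)
```

Reading the funnel: 30 null features plus 3 planted features plus
missingness flags give 66 prepared columns; 47 carry some predictive signal;
the KG stage removes `alcohol_intake` (its linked entity is 1-hop from the
target, reason `all-linked-1hop`); the literature stage removes
`shoe_size_marker` (500 co-mentions, under-representation p ≈ 1, reason
`known`); the scripted annotator scores the rest and the truly novel planted
risk factor `serum_urate` ranks first on the importance tie-break.
`summary(scr)` tabulates the per-stage verdict reasons;
`screen_write(scr, dir)` writes `selected.csv`, `funnel.csv` and
`run_meta.json`.

The evaluation functions work standalone, e.g. a 95% Wilson interval for 58
post-cutoff links out of 274:

```r
wilson_ci(58, 274)
#>     lower     upper
#> 0.1674670 0.2638633     # 21% [17, 26] as integer percents
```

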