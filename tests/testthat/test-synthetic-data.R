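test_that("null cohort hits the requested prevalence", {
  spec <- synthetic_spec(2000, 10, 0.1, seed = 3)
  gen <- generate_cohort(spec)
  p_hat <- mean(gen$cohort$data$target)
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(p_hat - 0.1), 3 * se)
  expect_true(all(!gen$truth$planted))
})

test_that("a planted effect is detectable by an independent logistic fit", {
  planted <- data.frame(feature = "risk_marker", effect = 1.0,
                        kg_known = FALSE, lit_known = FALSE)
  spec <- synthetic_spec(2000, 5, 0.1, planted, seed = 7)
  gen <- generate_cohort(spec)
  d <- gen$cohort$data
  # oracle: brute-force univariate logistic regression
  fit <- glm(target ~ risk_marker, data = d, family = binomial())
  p_logit <- summary(fit)$coefficients["risk_marker", 4]
  expect_lt(p_logit, 0.01)
  expect_gt(coef(fit)["risk_marker"], 0)
  # and the package's own univariate test agrees on detection
  expect_lt(univariate_pvalue(d$risk_marker, d$target), 0.01)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(500, 8, 0.15, small_planted(),
                         missing_rate = 0.1, seed = 42)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(g1, g2)
  g3 <- generate_cohort(synthetic_spec(500, 8, 0.15, small_planted(),
                                       missing_rate = 0.1, seed = 43))
  expect_false(identical(g1$cohort$data, g3$cohort$data))
})

test_that("cohorts too small to realize the prevalence are rejected", {
  expect_error(synthetic_spec(50, 5, 0.1), "expected cases")
  expect_error(synthetic_spec(1000, 5, 1.2))
  planted_dup <- data.frame(feature = c("a", "a"), effect = c(1, 1),
                            kg_known = FALSE, lit_known = FALSE)
  expect_error(synthetic_spec(1000, 5, 0.1, planted_dup), "duplicate")
})

test_that("missingness is injected at the requested MCAR rate", {
  spec <- synthetic_spec(2000, 20, 0.1, missing_rate = 0.2, seed = 5)
  gen <- generate_cohort(spec)
  feats <- gen$cohort$features
  rate <- mean(is.na(as.matrix(gen$cohort$data[feats])))
  expect_lt(abs(rate - 0.2), 0.01)
  expect_false(anyNA(gen$cohort$data$target))
})

test_that("toy KG files carry known pairs verbatim plus background edges", {
  ents <- paste0("C", 1:8)
  f_empty <- generate_toy_kg(ents, NULL, n_background = 12, seed = 1)
  raw <- read.csv(f_empty)
  expect_gt(nrow(raw), 0)
  known <- data.frame(a = "C1", b = "C2", n_citations = 1, first_year = 2015)
  f <- generate_toy_kg(ents, known, n_background = 5, seed = 2)
  raw <- read.csv(f)
  hit <- raw[(raw$subject_cui == "C1" & raw$object_cui == "C2") |
               (raw$subject_cui == "C2" & raw$object_cui == "C1"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_citations, 1)
  # a single-citation pair is present in the file but fails the evidence rule
  kg <- load_kg(f, min_citations = 2)
  expect_false(kg_adjacent(kg, "C1", "C2"))
  conflicting <- data.frame(a = c("C1", "C2"), b = c("C2", "C1"),
                            n_citations = c(2, 2),
                            first_year = c(2000, 2010))
  expect_error(generate_toy_kg(ents, conflicting, seed = 1), "conflicting")
  expect_error(generate_toy_kg(c("C1", "C1"), NULL), "duplicate")
})

test_that("post-cutoff known pairs are counted by temporal validation", {
  ents <- c("Cfeat", "Ctarget", "Cbg1", "Cbg2")
  known <- data.frame(a = "Cfeat", b = "Ctarget",
                      n_citations = 3, first_year = 2015)
  kg <- load_kg(generate_toy_kg(ents, known, n_background = 0, seed = 1))
  links <- list(f1 = data.frame(entity_id = "Cfeat", sim = 1, strong = TRUE))
  tv <- temporal_validation("f1", links, "Ctarget", kg, cutoff_year = 2011)
  expect_equal(tv$n_post, 1)
})

test_that("literature count tables enforce their invariants", {
  prov <- generate_literature_counts(c(gout = 5000, urate = 100),
                                     corpus_size = 37e6)
  expect_equal(prov$count("no such term"), 0)
  expect_equal(prov$count("Gout"), 5000) # normalized match
  expect_equal(prov$count_pair("gout", "urate"), 0)
  bad_pair <- data.frame(term_a = "urate", term_b = "gout", pair_count = 500)
  expect_error(generate_literature_counts(c(gout = 5000, urate = 100),
                                          bad_pair), "exceeds")
  expect_error(generate_literature_counts(c(gout = 5000), corpus_size = 100),
               "corpus")
})

test_that("scripted annotation providers validate and replay their script", {
  expect_error(scripted_llm_provider(list(c1 = c(5, 3, 3))), "1..4")
  prov <- scripted_llm_provider(list(c1 = c(3, 3, 3)),
                                default = c(2, 2, 2),
                                malform = "c_bad")
  ann <- parse_annotation(prov$complete("CANDIDATE-ID: c1\n..."))
  expect_equal(ann$interestingness, 3)
  expect_true(binarize(ann$interestingness))
  ann_def <- parse_annotation(prov$complete("CANDIDATE-ID: c_other\n"))
  expect_equal(ann_def$novelty, 2)
  expect_error(parse_annotation(prov$complete("CANDIDATE-ID: c_bad\n")),
               class = "annotation_parse_error")
  strict <- scripted_llm_provider(list(c1 = c(3, 3, 3)))
  expect_error(strict$complete("CANDIDATE-ID: c_unknown\n"), "unscripted")
})
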