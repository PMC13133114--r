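toy_corpus <- function() {
  c(doc_both = "serum urate level and gout risk in a prospective cohort",
    doc_one = "gout management guidelines for clinicians",
    doc_neither = "unrelated assay calibration methods paper")
}

test_that("retrieval ranks term-matching documents first and is deterministic", {
  idx <- bm25_index(toy_corpus())
  out <- retrieve_context("serum urate gout", idx, k = 32)
  expect_equal(nrow(out), 3)        # k larger than the corpus returns all
  expect_equal(out$doc_id[1], "doc_both")
  expect_gt(out$score[1], out$score[3])
  expect_equal(out$score[3], 0)     # no query term in doc_neither
  out2 <- retrieve_context("serum urate gout", idx, k = 32)
  expect_identical(out, out2)
  empty <- retrieve_context("anything", character(0))
  expect_equal(nrow(empty), 0)
})

test_that("bm25 scoring matches a hand-built single-term oracle", {
  docs <- c(d1 = "urate urate crystal", d2 = "urate response", d3 = "nothing here")
  idx <- bm25_index(docs)
  got <- retrieve_context("urate", idx, k = 3)
  # oracle: Okapi formula computed directly
  n <- 3; df <- 2; k1 <- 1.5; b <- 0.75
  idf <- log(1 + (n - df + 0.5) / (df + 0.5))
  lens <- c(3, 2, 2); avgdl <- mean(lens)
  sc <- function(f, len) idf * f * (k1 + 1) / (f + k1 * (1 - b + b * len / avgdl))
  expect_equal(got$score[got$doc_id == "d1"], sc(2, 3), tolerance = 1e-12)
  expect_equal(got$score[got$doc_id == "d2"], sc(1, 2), tolerance = 1e-12)
  expect_equal(got$doc_id[1], "d1")
})

test_that("prompts carry the hypothesis slots and tolerate missing context", {
  cand <- list(id = "f1", feature_name = "serum urate",
               target_name = "gout", direction = "negative",
               statistics = c(pval = 0.01))
  p <- build_prompt(cand, NULL)
  expect_match(p, "negative correlation")
  expect_match(p, "CANDIDATE-ID: f1")
  expect_false(grepl("Retrieved context", p))
  ctx <- retrieve_context("serum urate gout", bm25_index(toy_corpus()), 2)
  p2 <- build_prompt(cand, ctx)
  expect_match(p2, "Retrieved context")
  expect_match(p2, "doc_both")
  cand_bad <- cand; cand_bad$direction <- ""
  expect_error(build_prompt(cand_bad), "slot")
  p3 <- build_prompt(cand, NULL, distractor_prompt_template())
  expect_match(p3, "persuasive justification")
})

test_that("annotation parsing validates structure and range", {
  ok <- "blah\nANSWER\nNOVELTY: 3\nPLAUSIBILITY: 4\nINTERESTINGNESS: 3\nEXPLANATION: mechanism X\nEND ANSWER"
  ann <- parse_annotation(ok)
  expect_equal(c(ann$novelty, ann$plausibility, ann$interestingness), c(3, 4, 3))
  expect_equal(ann$confidence, 3)
  expect_match(ann$explanation, "mechanism X")
  expect_error(parse_annotation(gsub("NOVELTY: 3", "NOVELTY: 5", ok)),
               class = "annotation_parse_error")
  expect_error(parse_annotation("no scores here"),
               class = "annotation_parse_error")
})

test_that("scripted scores survive the prompt -> provider -> parse round trip", {
  set.seed(2)
  ids <- sprintf("cand%02d", 1:20)
  script <- lapply(ids, function(i)
    as.list(setNames(sample(1:4, 3, replace = TRUE),
                     c("novelty", "plausibility", "interestingness"))))
  names(script) <- ids
  prov <- scripted_llm_provider(script)
  cands <- data.frame(id = ids, feature_name = paste("feature", ids),
                      target_name = "gout", direction = "positive",
                      stringsAsFactors = FALSE)
  out <- annotate_candidates(cands, prov)
  expect_true(all(out$annotated))
  for (i in seq_along(ids)) {
    expect_equal(out$novelty[i], script[[ids[i]]]$novelty)
    expect_equal(out$interestingness[i], script[[ids[i]]]$interestingness)
  }
})

test_that("unparseable completions are retried then flagged, not dropped", {
  prov <- scripted_llm_provider(list(good = c(3, 3, 3)), malform = "bad")
  cands <- data.frame(id = c("good", "bad"),
                      feature_name = c("f good", "f bad"),
                      target_name = "gout", direction = "positive",
                      stringsAsFactors = FALSE)
  out <- annotate_candidates(cands, prov, max_retries = 2)
  expect_true(out$annotated[1])
  expect_false(out$annotated[2])
  expect_true(is.na(out$interestingness[2]))
})

test_that("binarization is strict at score 2", {
  expect_false(binarize(2))
  expect_true(binarize(3))
  expect_true(binarize(4))
  expect_false(binarize(1))
  expect_error(binarize(5), "1-4")
})

test_that("selection keeps scores above 2, ranks by confidence then fimp", {
  set.seed(5)
  ann <- data.frame(id = sprintf("c%02d", 1:40),
                    interestingness = c(rep(3, 31), rep(2, 9)),
                    confidence = c(rep(3, 31), rep(2, 9)),
                    fimp = runif(40), stringsAsFactors = FALSE)
  sel <- select_candidates(ann, top_k = 30)
  expect_equal(nrow(sel), 30)
  expect_true(all(sel$interestingness > 2))
  # ranked by fimp within equal confidence
  expect_true(all(diff(sel$fimp) <= 0))
  # the lowest-fimp eligible candidate is the one truncated away
  eligible <- ann[ann$interestingness > 2, ]
  expect_false(eligible$id[which.min(eligible$fimp)] %in% sel$id)

  flat <- data.frame(id = c("a", "b"), interestingness = 2, confidence = 2,
                     fimp = c(1, 2))
  expect_equal(nrow(select_candidates(flat)), 0)

  tie <- data.frame(id = c("a", "b"), interestingness = c(3, 3),
                    confidence = c(3, 3), fimp = c(0.1, 0.9))
  expect_equal(select_candidates(tie)$id, c("b", "a"))
  # idempotent: selecting from a selection changes nothing
  sel2 <- select_candidates(sel, top_k = 30)
  expect_equal(sel2$id, sel$id)
  expect_true(all(sel$id %in% ann$id))
})
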