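test_that("univariate p-values behave across feature types", {
  y <- rep(c(0, 1), each = 50)
  expect_warning(p_const <- univariate_pvalue(rep(2, 100), y), "constant")
  expect_equal(p_const, 1)
  # x identical in both classes
  x_same <- rep(c(1, 2), 50)
  expect_gt(univariate_pvalue(x_same, y), 0.99)
  # perfect binary predictor vs the exact 2x2 oracle
  x_perf <- y
  p_pkg <- univariate_pvalue(x_perf, y)
  p_oracle <- fisher.test(table(x_perf, y))$p.value
  expect_lt(p_oracle, 1e-10)
  expect_lt(p_pkg, 1e-10)
  # sparse 2x2 goes down the exact-test path and equals the oracle
  x_rare <- c(rep(1, 3), rep(0, 97))
  expect_equal(univariate_pvalue(x_rare, y),
               fisher.test(table(x_rare, y))$p.value)
  # continuous shift detected by the Welch path
  set.seed(9)
  x_cont <- rnorm(100) + 0.8 * y
  expect_lt(univariate_pvalue(x_cont, y), 0.01)
  expect_error(univariate_pvalue(rnorm(3), c(0, 0, 0)), "each class")
})

test_that("the p-value pass rule is strict at the threshold", {
  scores <- data.frame(feature = c("a", "b"), pval = c(0.19, 0.2),
                       mi = 0, fimp = 0)
  out <- apply_utility_filter(scores, utility_config(theta_p = 0.2))
  expect_true(out$pass_pval[1])
  expect_false(out$pass_pval[2])
})

test_that("mutual information matches a direct entropy computation", {
  y <- rep(c(0, 1), each = 100)
  expect_equal(mutual_information(rep(1, 200), y), 0)
  expect_equal(mutual_information(y, y), log(2), tolerance = 1e-12)
  # oracle: H(X) + H(Y) - H(X,Y) on the binned joint table
  set.seed(4)
  x <- rnorm(500) + 0.5 * rep(c(0, 1), 250)
  yy <- rep(c(0, 1), 250)
  mi_pkg <- mutual_information(x, yy, n_bins = 10)
  bx <- as.integer(cut(x, breaks = unique(quantile(x, seq(0, 1, 0.1))),
                       include.lowest = TRUE))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- as.numeric(table(bx, yy)) / length(x)
  mi_oracle <- ent(as.numeric(table(bx)) / length(x)) +
    ent(as.numeric(table(yy)) / length(x)) - ent(pj)
  expect_equal(mi_pkg, mi_oracle, tolerance = 1e-12)
  expect_gte(mi_pkg, 0)
})

test_that("model attributions rank a planted feature first and are additive", {
  ranks <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 300
    X <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
    y <- rbinom(n, 1, plogis(-1 + 2 * X[, "f01"]))
    if (sum(y) < 10) y[sample(n, 10)] <- 1
    fimp <- model_importance(X, y, seed = s, nrounds = 30)
    names(which.max(fimp))
  }, character(1))
  expect_gte(sum(ranks == "f01"), 9)

  set.seed(77)
  X <- matrix(rnorm(120 * 4), 120, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rbinom(120, 1, plogis(X[, 1]))
  det <- model_importance(X, y, seed = 5, nrounds = 25, details = TRUE)
  # additivity: per-sample attributions + bias reproduce the margin
  expect_lt(max(abs(rowSums(det$contrib) - det$margin)), 1e-5)
  expect_setequal(names(det$fimp), colnames(X))
  # dropped feature has no importance entry
  fimp3 <- model_importance(X[, 1:3], y, seed = 5, nrounds = 25)
  expect_false("g4" %in% names(fimp3))
  expect_error(model_importance(X, rep(1, 120), seed = 1), "single-class")
  expect_identical(model_importance(X, y, seed = 5, nrounds = 25),
                   model_importance(X, y, seed = 5, nrounds = 25))
})

test_that("the utility verdict combines the three criteria as configured", {
  scores <- data.frame(feature = "x", pval = 0.5, mi = 0, fimp = 2e-4)
  expect_true(apply_utility_filter(scores, utility_config())$pass_utility)
  scores$fimp <- 0
  expect_false(apply_utility_filter(scores, utility_config())$pass_utility)
  # conjunction never passes more than disjunction
  set.seed(3)
  tab <- data.frame(feature = sprintf("f%d", 1:200),
                    pval = runif(200), mi = runif(200, 0, 2e-3),
                    fimp = runif(200, 0, 2e-4))
  n_any <- sum(apply_utility_filter(tab, utility_config(mode = "any"))$pass_utility)
  n_all <- sum(apply_utility_filter(tab, utility_config(mode = "all"))$pass_utility)
  expect_lte(n_all, n_any)
  all_set <- tab$feature[apply_utility_filter(tab, utility_config(mode = "all"))$pass_utility]
  any_set <- tab$feature[apply_utility_filter(tab, utility_config(mode = "any"))$pass_utility]
  expect_true(all(all_set %in% any_set))
})

test_that("loosening any threshold never shrinks the pass set", {
  set.seed(8)
  tab <- data.frame(feature = sprintf("f%d", 1:300),
                    pval = runif(300), mi = runif(300, 0, 2e-3),
                    fimp = runif(300, 0, 2e-4))
  base <- utility_config()
  passes <- function(cfg) tab$feature[apply_utility_filter(tab, cfg)$pass_utility]
  for (loose in list(utility_config(theta_p = 0.5),
                     utility_config(theta_mi = 1e-4),
                     utility_config(theta_fimp = 1e-5))) {
    expect_true(all(passes(base) %in% passes(loose)))
  }
})

test_that("threshold sensitivity recall is non-increasing in stringency", {
  scores <- data.frame(feature = c("strong", "mid", "weak"),
                       pval = c(1e-5, 0.005, 0.15),
                       mi = 0, fimp = 0)
  cfg <- utility_config()
  sens <- threshold_sensitivity(scores, c("strong", "mid", "weak"),
                                c(0.2, 0.01, 0.001), cfg)
  expect_true(all(diff(sens$recall) <= 0))
  # the p = 0.005 feature is recalled at 0.2 and 0.01 but not 0.001
  sens_mid <- threshold_sensitivity(scores, "mid", c(0.2, 0.01, 0.001), cfg)
  expect_equal(sens_mid$recall, c(1, 1, 0))
  expect_equal(threshold_sensitivity(scores, "absent", 0.2, cfg)$recall, 0)
  expect_error(threshold_sensitivity(scores, character(), 0.2, cfg), "empty")
})
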