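#' Utility filter configuration
#'
#' Deliberately lenient defaults: the utility screen is a liberal first pass
#' meant to discard only features with no predictive signal at all, so that
#' potentially interesting borderline features survive to the novelty
#' stages.
#'
#' @param theta_p Univariate p-value threshold (pass when p strictly below).
#' @param theta_mi Mutual information threshold in nats (pass when >=).
#' @param theta_fimp Model-attribution threshold (pass when >=).
#' @param mode `"any"` (disjunction, default) or `"all"` (conjunction) of
#'   the three criteria.
#' @param n_bins Quantile bins used to discretize continuous features for
#'   the MI estimate.
#' @param seed Seed for the boosted model.
#' @param nrounds,nfolds Boosting rounds and cross-validation folds for the
#'   attribution model.
#' @return Object of class `utility_config`.
#' @export
utility_config <- function(theta_p = 0.2, theta_mi = 1e-3, theta_fimp = 1e-4,
                           mode = c("any", "all"), n_bins = 10L, seed = 1L,
                           nrounds = 50L, nfolds = 3L) {
  mode <- match.arg(mode)
  stopifnot(theta_p > 0, theta_mi > 0, theta_fimp > 0, n_bins >= 2,
            nrounds >= 1, nfolds >= 2)
  structure(list(theta_p = theta_p, theta_mi = theta_mi,
                 theta_fimp = theta_fimp, mode = mode,
                 n_bins = as.integer(n_bins), seed = as.integer(seed),
                 nrounds = as.integer(nrounds), nfolds = as.integer(nfolds)),
            class = "utility_config")
}

#' Univariate association p-value between a feature and a binary target
#'
#' Two-sided test chosen by feature type: continuous features are compared
#' between outcome classes with a Welch two-sample t-test; binary and other
#' low-cardinality features (at most `max_levels` distinct values) with a
#' chi-square test of independence, switching to Fisher's exact test when
#' any expected cell count falls below 5. Constant features carry no
#' information and return p = 1 with a warning.
#'
#' @param x Feature column (numeric; missing values dropped pairwise).
#' @param y Binary 0/1 target.
#' @param max_levels Distinct-value cutoff for the discrete path, default 5.
#' @return Two-sided p-value.
#' @export
univariate_pvalue <- function(x, y, max_levels = 5L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("univariate_pvalue: need >= 2 observations in each class")
  ux <- unique(x)
  if (length(ux) < 2) {
    warning("univariate_pvalue: constant feature, p = 1")
    return(1)
  }
  if (length(ux) <= max_levels) {
    tab <- table(x, y)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5))
      return(fisher.test(tab)$p.value)
    return(suppressWarnings(chisq.test(tab, correct = FALSE))$p.value)
  }
  tryCatch(t.test(x[y == 1], x[y == 0], var.equal = FALSE)$p.value,
           error = function(e) {
             # both groups internally constant: separation if means differ
             if (mean(x[y == 1]) == mean(x[y == 0])) 1 else 0
           })
}

# Quantile-bin a vector into at most n_bins groups (integer codes).
quantile_bin <- function(x, n_bins) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(match(x, sort(ux)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Plug-in mutual information between a feature and a binary target
#'
#' Continuous features are discretized into quantile bins, then the plug-in
#' estimate sum p(a,b) log\[p(a,b) / (p(a) p(b))\] is computed over the
#' joint contingency table, in nats. Degenerate binning (a single bin)
#' yields 0.
#'
#' @param x Feature column.
#' @param y Binary target.
#' @param n_bins Maximum quantile bins for continuous features, default 10.
#' @return Mutual information in nats (>= 0 up to floating point).
#' @export
mutual_information <- function(x, y, n_bins = 10L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  bx <- quantile_bin(x, n_bins)
  tab <- table(bx, y)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  max(sum(terms[p > 0]), 0)
}

#' Model-based feature importance from boosted-tree attributions
#'
#' Trains a gradient-boosted tree classifier (xgboost, logistic objective)
#' under k-fold cross-validation and computes, for every row of its
#' held-out fold, the per-sample additive feature attributions
#' (TreeSHAP, `predcontrib`). A feature's importance is the global mean of
#' its absolute per-sample attribution. Deterministic under `seed`
#' (single-threaded training, seeded fold assignment).
#'
#' @param X Numeric feature matrix or data frame (>= 50 rows).
#' @param y Binary 0/1 target with >= 10 positives.
#' @param seed Integer seed.
#' @param nrounds Boosting rounds per fold, default 50.
#' @param nfolds Cross-validation folds, default 3.
#' @param max_depth,eta Tree depth and learning rate.
#' @param details If TRUE, also return the held-out attribution matrix
#'   (including the bias column) and the matching margin predictions, so the
#'   additivity of the attributions can be verified.
#' @return Named numeric vector of importances (one per column of `X`), or,
#'   with `details = TRUE`, a list `fimp`, `contrib`, `margin`.
#' @export
model_importance <- function(X, y, seed = 1L, nrounds = 50L, nfolds = 3L,
                             max_depth = 4L, eta = 0.3, details = FALSE) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 50) stop("model_importance: need >= 50 rows")
  if (length(unique(y)) < 2) stop("model_importance: single-class target")
  if (sum(y == 1) < 10) stop("model_importance: need >= 10 positives")
  folds <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(X))))
  contrib <- matrix(NA_real_, nrow(X), ncol(X) + 1L,
                    dimnames = list(NULL, c(colnames(X), "(Intercept)")))
  margin <- numeric(nrow(X))
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = seed)
  for (k in seq_len(nfolds)) {
    tr <- folds != k; te <- !tr
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                nthread = 1)
    dte <- xgboost::xgb.DMatrix(X[te, , drop = FALSE], nthread = 1)
    booster <- xgboost::xgb.train(params = params, data = dtr,
                                  nrounds = nrounds, verbose = 0)
    contrib[te, ] <- predict(booster, dte, predcontrib = TRUE)
    margin[te] <- predict(booster, dte, outputmargin = TRUE)
  }
  fimp <- colMeans(abs(contrib[, seq_len(ncol(X)), drop = FALSE]))
  if (details) list(fimp = fimp, contrib = contrib, margin = margin)
  else fimp
}

#' Score every feature by the three utility criteria
#'
#' @param ct `cohort_table` (prepared: imputed, deduplicated).
#' @param config `utility_config`.
#' @return Data frame (one row per feature): `feature`, `pval`, `mi`,
#'   `fimp`, pass flags and `pass_utility`, plus `direction`
#'   (sign of association, see [effect_direction()]).
#' @export
utility_scores <- function(ct, config = utility_config()) {
  stopifnot(inherits(ct, "cohort_table"), inherits(config, "utility_config"))
  y <- ct$data[[ct$target]]
  feats <- ct$features
  pval <- vapply(feats, function(f)
    suppressWarnings(univariate_pvalue(ct$data[[f]], y)), numeric(1))
  mi <- vapply(feats, function(f)
    mutual_information(ct$data[[f]], y, config$n_bins), numeric(1))
  fimp <- model_importance(ct$data[feats], y, seed = config$seed,
                           nrounds = config$nrounds, nfolds = config$nfolds)
  direction <- vapply(feats, function(f)
    suppressWarnings(effect_direction(ct$data[[f]], y)), character(1))
  scores <- data.frame(feature = feats, pval = pval, mi = mi,
                       fimp = as.numeric(fimp[feats]),
                       direction = direction,
                       stringsAsFactors = FALSE, row.names = NULL)
  apply_utility_filter(scores, config)
}

#' Apply the utility pass/fail rule to a score table
#'
#' Pass flags: `pval < theta_p` (strict), `mi >= theta_mi`,
#' `fimp >= theta_fimp`; `pass_utility` is their disjunction
#' (`mode = "any"`) or conjunction (`mode = "all"`).
#'
#' @param scores Data frame with columns `pval`, `mi`, `fimp`.
#' @param config `utility_config`.
#' @return `scores` with the four pass flags added/recomputed.
#' @export
apply_utility_filter <- function(scores, config = utility_config()) {
  stopifnot(all(c("pval", "mi", "fimp") %in% names(scores)))
  scores$pass_pval <- scores$pval < config$theta_p
  scores$pass_mi <- scores$mi >= config$theta_mi
  scores$pass_fimp <- scores$fimp >= config$theta_fimp
  scores$pass_utility <- if (config$mode == "any")
    scores$pass_pval | scores$pass_mi | scores$pass_fimp
  else scores$pass_pval & scores$pass_mi & scores$pass_fimp
  scores
}

#' Sign of a feature's association with the binary target
#'
#' Point-biserial correlation sign for continuous features; for binary
#' features this equals the sign of the log-odds association. An exactly
#' zero association returns `"positive"` with a warning.
#'
#' @param x Feature column (non-constant).
#' @param y Binary target.
#' @return `"positive"` or `"negative"`.
#' @export
effect_direction <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) stop("effect_direction: constant feature")
  r <- cor(x, y)
  if (is.na(r) || r == 0) {
    warning("effect_direction: zero-magnitude association; reporting positive")
    return("positive")
  }
  if (r > 0) "positive" else "negative"
}

#' Utility-filter recall over a threshold grid
#'
#' Recomputes the utility pass set at each p-value threshold in the grid
#' and reports the fraction of a reference feature set retained — the
#' screen's sensitivity analysis. Recall is non-increasing as the threshold
#' tightens.
#'
#' @param scores Utility score table from [utility_scores()].
#' @param reference_set Nonempty character vector of feature ids.
#' @param theta_p_grid P-value thresholds to evaluate.
#' @param config Base `utility_config` (other thresholds held fixed).
#' @return Data frame `theta_p`, `recall`.
#' @export
threshold_sensitivity <- function(scores, reference_set,
                                  theta_p_grid = c(0.2, 0.01, 0.001),
                                  config = utility_config()) {
  if (length(reference_set) == 0)
    stop("threshold_sensitivity: empty reference set")
  recall <- vapply(theta_p_grid, function(tp) {
    cfg <- config
    cfg$theta_p <- tp
    sc <- apply_utility_filter(scores, cfg)
    passed <- sc$feature[sc$pass_utility]
    mean(reference_set %in% passed)
  }, numeric(1))
  data.frame(theta_p = theta_p_grid, recall = recall)
}
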