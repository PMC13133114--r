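#' Wilson score confidence interval for a binomial proportion
#'
#' Score-test-inversion interval; unlike the Wald interval it is well behaved
#' at the boundaries (k = 0 or k = n) and never escapes \[0, 1\].
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` of proportions.
#' @examples
#' wilson_ci(58, 274) # about [0.17, 0.26]
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, is.finite(k), is.finite(n))
  if (n <= 0) stop("wilson_ci: n must be > 0")
  if (k < 0 || k > n) stop("wilson_ci: k must satisfy 0 <= k <= n")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- c(lower = centre - half, upper = centre + half)
  # the interval is exact at the boundaries; avoid cancellation noise
  if (k == 0) out[["lower"]] <- 0
  if (k == n) out[["upper"]] <- 1
  pmin(pmax(out, 0), 1)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, whose point probability does not exceed
#' the observed table's.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return p-value.
#' @export
fisher_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("fisher_two_sided: empty margin, p = 1")
    return(1)
  }
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa (po - pe) / (1 - pe) over the union of observed
#' categories. When both raters are constant and identical, chance agreement
#' pe = 1 and kappa is returned as 1 by convention (with a warning).
#'
#' @param r1,r2 Equal-length vectors of categorical ratings.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) > 0)
  cats <- sort(unique(c(r1, r2)))
  f1 <- factor(r1, levels = cats)
  f2 <- factor(r2, levels = cats)
  tab <- table(f1, f2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("cohens_kappa: both raters constant and equal; kappa = 1 by convention")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Fraction of agreeing binarized annotations
#'
#' @param model_flags,human_flags Equal-length logical vectors.
#' @return Mean elementwise equality.
#' @export
binarized_agreement <- function(model_flags, human_flags) {
  stopifnot(length(model_flags) == length(human_flags))
  if (length(model_flags) == 0) stop("binarized_agreement: empty input")
  mean(model_flags == human_flags)
}

#' Inject distractor candidates into an annotation set
#'
#' Samples `ceiling(frac * nrow(real))` distractors without replacement from
#' a pool of candidates that failed the utility filter, shuffles them in with
#' the real candidates, and returns the combined set plus the hidden labels.
#' Used to measure whether annotators can tell pipeline output from utility
#' rejects.
#'
#' @param real Data frame of real candidates with a `candidate_id` column
#'   (a character vector of ids is also accepted).
#' @param discarded_pool Pool of discarded candidates, same format.
#' @param frac Distractor fraction relative to the real set, default 0.2.
#' @param seed Integer seed; sampling and shuffling are deterministic.
#' @return List with `combined` (data frame, shuffled) and `hidden_labels`
#'   (named logical, TRUE = distractor).
#' @export
inject_distractors <- function(real, discarded_pool, frac = 0.2, seed = 1L) {
  as_cand <- function(x) {
    if (is.data.frame(x)) {
      stopifnot("candidate_id" %in% names(x))
      x
    } else data.frame(candidate_id = as.character(x), stringsAsFactors = FALSE)
  }
  real <- as_cand(real)
  pool <- as_cand(discarded_pool)
  n_d <- ceiling(frac * nrow(real))
  if (n_d > nrow(pool)) stop("inject_distractors: pool smaller than required distractor count")
  if (any(pool$candidate_id %in% real$candidate_id))
    stop("inject_distractors: pool overlaps real candidate ids")
  with_seed(seed, {
    picked <- pool[sample.int(nrow(pool), n_d), , drop = FALSE]
    shared <- intersect(names(real), names(picked))
    combined <- rbind(real[, shared, drop = FALSE], picked[, shared, drop = FALSE])
    ord <- sample.int(nrow(combined))
    combined <- combined[ord, , drop = FALSE]
    rownames(combined) <- NULL
    labels <- setNames(combined$candidate_id %in% picked$candidate_id,
                       combined$candidate_id)
    list(combined = combined, hidden_labels = labels)
  })
}

#' Welch two-sample t-test p-value
#'
#' Two-sided, unequal-variance comparison of group means. When both groups
#' are degenerate (zero variance) with equal means the p-value is 1.
#'
#' @param a,b Numeric score vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    return(0)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Normalized discounted cumulative gain
#'
#' DCG with linear gain in the graded relevance (expert ratings 1-4) and
#' 1/log2(rank + 1) discount, normalized by the DCG of the ideal (sorted)
#' ordering.
#'
#' @param ranked_relevances Relevance scores in presented rank order.
#' @return NDCG in \[0, 1\].
#' @export
ndcg <- function(ranked_relevances) {
  rel <- as.numeric(ranked_relevances)
  stopifnot(length(rel) > 0, all(rel >= 0))
  if (all(rel == 0)) {
    warning("ndcg: all relevances zero; defined as 0")
    return(0)
  }
  disc <- 1 / log2(seq_along(rel) + 1)
  dcg <- sum(rel * disc)
  idcg <- sum(sort(rel, decreasing = TRUE) * disc)
  dcg / idcg
}

#' Mean reciprocal rank (single ranking)
#'
#' Reciprocal rank of the first relevant item. Input may be a logical vector
#' of relevance flags or numeric ratings, in which case ratings >= 3 count as
#' relevant.
#'
#' @param ranked_flags Relevance flags (or 1-4 ratings) in rank order.
#' @param relevance_threshold Rating threshold when numeric input is given.
#' @return 1/rank of first relevant item; 0 with a warning if none.
#' @export
mrr <- function(ranked_flags, relevance_threshold = 3) {
  if (is.numeric(ranked_flags)) ranked_flags <- ranked_flags >= relevance_threshold
  stopifnot(is.logical(ranked_flags), length(ranked_flags) > 0)
  idx <- which(ranked_flags)
  if (length(idx) == 0) {
    warning("mrr: no relevant item; returning 0")
    return(0)
  }
  1 / idx[1]
}
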