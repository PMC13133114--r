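#' Literature count record for a feature-target pair
#'
#' @param n_x Feature-term hit count.
#' @param n_y Target-term hit count.
#' @param n_xy Co-mention count.
#' @param N Corpus size (number of documents).
#' @return Object of class `literature_counts`.
#' @export
literature_counts <- function(n_x, n_y, n_xy, N) {
  vals <- c(n_x = n_x, n_y = n_y, n_xy = n_xy, N = N)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("literature_counts: counts must be finite non-negative integers")
  if (n_xy > min(n_x, n_y))
    stop("literature_counts: n_xy cannot exceed min(n_x, n_y)")
  if (n_x > N || n_y > N)
    stop("literature_counts: term counts cannot exceed corpus size N")
  structure(as.list(vals), class = "literature_counts")
}

#' Literature filter configuration
#'
#' Deliberately relaxed defaults: the filter is meant to discard only
#' clearly established pairs while retaining borderline cases.
#'
#' @param theta_lit Absolute co-mention threshold (retain if n_xy below it).
#' @param theta_pval Under-representation p-value threshold.
#' @param min_feature_hits Feature terms with fewer hits than this bypass the
#'   filter entirely (e.g. recently coined terms).
#' @param corpus_size Document-universe size for the exact test.
#' @return Object of class `lit_config`.
#' @export
lit_config <- function(theta_lit = 4, theta_pval = 0.4, min_feature_hits = 20,
                       corpus_size = 37e6) {
  stopifnot(theta_lit > 0, theta_pval > 0, min_feature_hits > 0, corpus_size > 0)
  structure(list(theta_lit = theta_lit, theta_pval = theta_pval,
                 min_feature_hits = min_feature_hits, corpus_size = corpus_size),
            class = "lit_config")
}

#' One-sided under-representation p-value for a co-mention count
#'
#' Tests whether two terms co-occur less often than expected by chance in a
#' corpus of N documents: the lower hypergeometric tail P(X <= n_xy) for
#' X ~ Hypergeometric(N, n_x, n_y), i.e. the one-way Fisher exact test with
#' alternative "less" on the 2x2 document table.
#'
#' @param counts A [literature_counts()] object.
#' @return p-value in (0, 1\].
#' @export
underrepresentation_pvalue <- function(counts) {
  stopifnot(inherits(counts, "literature_counts"))
  if (counts$n_x + counts$n_y - counts$n_xy > counts$N)
    stop("underrepresentation_pvalue: counts exceed corpus size")
  phyper(counts$n_xy, m = counts$n_x, n = counts$N - counts$n_x, k = counts$n_y)
}

#' Literature-based novelty decision for a feature-target pair
#'
#' A pair is retained (treated as not yet established) when any of:
#' the feature term is rare (`n_x < min_feature_hits`), the co-mention count
#' is below the absolute threshold, or co-occurrence is significantly
#' under-represented relative to chance.
#'
#' @param counts A [literature_counts()] object.
#' @param config A [lit_config()] object.
#' @return List with `retain` (flag), `reason` (one of `rare-feature`,
#'   `few-comentions`, `underrepresented`, `known`) and `pval` (NA when not
#'   computed).
#' @export
literature_filter <- function(counts, config = lit_config()) {
  stopifnot(inherits(counts, "literature_counts"), inherits(config, "lit_config"))
  if (counts$n_x < config$min_feature_hits)
    return(list(retain = TRUE, reason = "rare-feature", pval = NA_real_))
  if (counts$n_xy < config$theta_lit)
    return(list(retain = TRUE, reason = "few-comentions", pval = NA_real_))
  p <- underrepresentation_pvalue(counts)
  if (p < config$theta_pval)
    return(list(retain = TRUE, reason = "underrepresented", pval = p))
  list(retain = FALSE, reason = "known", pval = p)
}

#' Offline literature count provider backed by in-memory tables
#'
#' Implements the count-provider interface (`count(term)`,
#' `count_pair(a, b)`, `corpus_size()`) from a named vector of term counts
#' and a data frame of pair co-mention counts. Terms are matched after
#' normalization (lowercase, collapsed whitespace); unknown terms count 0.
#'
#' @param term_counts Named numeric vector: term -> hit count.
#' @param pair_counts Data frame with columns `term_a`, `term_b`,
#'   `pair_count`; order of a/b is ignored. May be NULL.
#' @param corpus_size Total document count N.
#' @return Provider: list of closures `count`, `count_pair`, `corpus_size`.
#' @export
lit_count_provider <- function(term_counts, pair_counts = NULL, corpus_size = 37e6) {
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  terms <- setNames(as.numeric(term_counts), norm(names(term_counts)))
  if (any(terms > corpus_size)) stop("lit_count_provider: term count exceeds corpus size")
  pkey <- function(a, b) paste(sort(c(norm(a), norm(b))), collapse = "\x1f")
  pairs <- new.env(parent = emptyenv())
  if (!is.null(pair_counts) && nrow(pair_counts) > 0) {
    stopifnot(all(c("term_a", "term_b", "pair_count") %in% names(pair_counts)))
    for (i in seq_len(nrow(pair_counts))) {
      a <- pair_counts$term_a[i]; b <- pair_counts$term_b[i]
      n_a <- terms[norm(a)]; n_b <- terms[norm(b)]
      cap <- min(n_a %||% 0, n_b %||% 0, na.rm = FALSE)
      if (is.na(cap)) cap <- Inf
      if (pair_counts$pair_count[i] > cap)
        stop("lit_count_provider: pair count exceeds min of term counts for (",
             a, ", ", b, ")")
      assign(pkey(a, b), pair_counts$pair_count[i], envir = pairs)
    }
  }
  list(
    count = function(term) {
      v <- terms[norm(term)]
      if (is.na(v)) 0 else unname(v)
    },
    count_pair = function(a, b) {
      v <- mget(pkey(a, b), envir = pairs, ifnotfound = 0)[[1]]
      unname(v)
    },
    corpus_size = function() corpus_size
  )
}

#' Read an offline literature count provider from CSV files
#'
#' @param term_file CSV with header `term,count`.
#' @param pair_file CSV with header `term_a,term_b,pair_count`, or NULL.
#' @param corpus_size Total document count N.
#' @return Provider as in [lit_count_provider()].
#' @export
lit_count_provider_csv <- function(term_file, pair_file = NULL, corpus_size = 37e6) {
  tc <- read.csv(term_file, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "count") %in% names(tc)))
  pc <- if (!is.null(pair_file)) read.csv(pair_file, stringsAsFactors = FALSE) else NULL
  lit_count_provider(setNames(tc$count, tc$term), pc, corpus_size)
}

#' Assemble literature counts for a feature-target pair from a provider
#'
#' @param provider Count provider (see [lit_count_provider()]).
#' @param feature_term,target_term Query terms.
#' @return A [literature_counts()] object.
#' @export
pair_counts <- function(provider, feature_term, target_term) {
  n_x <- provider$count(feature_term)
  n_y <- provider$count(target_term)
  n_xy <- provider$count_pair(feature_term, target_term)
  literature_counts(n_x, n_y, min(n_xy, n_x, n_y), provider$corpus_size())
}
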