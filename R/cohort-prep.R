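#' Construct a cohort feature table
#'
#' Thin S3 container around a participant-level data frame: a binary
#' `target` column, baseline covariates (default `age`, `sex`, `bmi`), and
#' every remaining column treated as a candidate feature. Per-feature
#' human-readable names/descriptions (used by the concept linker) live in
#' `meta`.
#'
#' @param data Data frame with the target, covariate and feature columns.
#' @param target Name of the binary outcome column, default `"target"`.
#' @param covariates Baseline covariate column names, default
#'   `c("age", "sex", "bmi")`.
#' @param meta Optional data frame `feature`, `name`, `description`;
#'   defaults to names derived from the column ids.
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(data, target = "target",
                         covariates = c("age", "sex", "bmi"), meta = NULL) {
  stopifnot(is.data.frame(data), target %in% names(data))
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov) > 0)
    stop("cohort_table: missing covariate column(s): ",
         paste(miss_cov, collapse = ", "))
  y <- data[[target]]
  if (!all(y %in% c(0, 1))) stop("cohort_table: target must be binary 0/1")
  features <- setdiff(names(data), c(target, covariates))
  if (anyDuplicated(features)) stop("cohort_table: duplicate feature names")
  if (is.null(meta)) {
    meta <- data.frame(feature = features,
                       name = gsub("[._]+", " ", features),
                       description = gsub("[._]+", " ", features),
                       stringsAsFactors = FALSE)
  }
  structure(list(data = data, target = target, covariates = covariates,
                 features = features, meta = meta),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table: ", nrow(x$data), " participants, ",
      length(x$features), " features, prevalence ",
      signif(mean(x$data[[x$target]]), 3), "\n", sep = "")
  invisible(x)
}

# Refresh the feature list and metadata after columns change.
refresh_features <- function(ct, keep = NULL) {
  ct$features <- setdiff(names(ct$data), c(ct$target, ct$covariates))
  extra <- setdiff(ct$features, ct$meta$feature)
  if (length(extra) > 0)
    ct$meta <- rbind(ct$meta,
                     data.frame(feature = extra,
                                name = gsub("[._]+", " ", extra),
                                description = gsub("[._]+", " ", extra),
                                stringsAsFactors = FALSE))
  ct$meta <- ct$meta[ct$meta$feature %in% ct$features, , drop = FALSE]
  rownames(ct$meta) <- NULL
  ct
}

#' Cohort preparation configuration
#'
#' @param min_nonmissing Minimum observed values a feature needs to be kept
#'   (default 30).
#' @param corr_threshold Pearson correlation above which the later of two
#'   features is dropped as redundant (default 0.9).
#' @param ipw_enabled Apply propensity-weighted negative downsampling?
#' @param ipw_ratio Negatives retained per positive (default 9, i.e. 9:1).
#' @param seed Seed for the downsampling draw.
#' @return Object of class `prep_config`.
#' @export
prep_config <- function(min_nonmissing = 30L, corr_threshold = 0.9,
                        ipw_enabled = FALSE, ipw_ratio = 9, seed = 1L) {
  stopifnot(min_nonmissing >= 1, corr_threshold > 0, corr_threshold <= 1,
            ipw_ratio >= 1)
  structure(list(min_nonmissing = as.integer(min_nonmissing),
                 corr_threshold = corr_threshold,
                 ipw_enabled = isTRUE(ipw_enabled),
                 ipw_ratio = ipw_ratio, seed = as.integer(seed)),
            class = "prep_config")
}

#' Mean-impute missing feature values and append missingness flags
#'
#' Every missing numeric value is replaced by the feature's observed mean;
#' each feature that had at least one missing value gains a companion binary
#' column `<name>__missing` (features with no missing values get no flag, so
#' no constant columns are created).
#'
#' @param ct `cohort_table`.
#' @return Imputed `cohort_table`.
#' @export
impute_and_flag <- function(ct) {
  stopifnot(inherits(ct, "cohort_table"))
  if (nrow(ct$data) == 0) stop("impute_and_flag: empty table")
  for (f in ct$features) {
    x <- ct$data[[f]]
    nmiss <- sum(is.na(x))
    if (nmiss == 0) next
    if (nmiss == length(x))
      stop("impute_and_flag: feature '", f,
           "' has zero observed values (drop sparse features first)")
    flag <- as.integer(is.na(x))
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    ct$data[[f]] <- x
    ct$data[[paste0(f, "__missing")]] <- flag
  }
  refresh_features(ct)
}

#' Drop features with too few observed values
#'
#' @param ct `cohort_table`.
#' @param min_nonmissing Minimum observed (non-missing) values; features
#'   with fewer are dropped (a feature with exactly this many is kept).
#' @return List: `table` (filtered `cohort_table`) and `dropped`
#'   (character vector of removed features).
#' @export
drop_sparse_features <- function(ct, min_nonmissing = 30L) {
  stopifnot(inherits(ct, "cohort_table"), min_nonmissing >= 1)
  nobs <- vapply(ct$features, function(f) sum(!is.na(ct$data[[f]])), integer(1))
  dropped <- names(nobs)[nobs < min_nonmissing]
  if (length(dropped) == length(ct$features))
    stop("drop_sparse_features: all features dropped")
  ct$data[dropped] <- NULL
  list(table = refresh_features(ct), dropped = dropped)
}

#' Drop near-duplicate features by pairwise correlation
#'
#' Greedy first-seen scan in declared column order: a feature is dropped
#' when its absolute Pearson correlation with an already-kept feature
#' exceeds the threshold; the kept partner and r are logged. Zero-variance
#' features are excluded from the screen and retained with a warning.
#'
#' @param ct `cohort_table` (features must be imputed/complete).
#' @param corr_threshold Drop when |r| strictly exceeds this (default 0.9).
#' @return List: `table` and `dropped_pairs` (data frame
#'   `kept`, `dropped`, `r`).
#' @export
drop_correlated <- function(ct, corr_threshold = 0.9) {
  stopifnot(inherits(ct, "cohort_table"), corr_threshold > 0, corr_threshold <= 1)
  feats <- ct$features
  sds <- vapply(feats, function(f) sd(ct$data[[f]], na.rm = TRUE), numeric(1))
  const <- feats[!is.na(sds) & sds == 0]
  if (length(const) > 0)
    warning("drop_correlated: constant feature(s) excluded from screen: ",
            paste(const, collapse = ", "))
  screen <- setdiff(feats, const)
  kept <- character()
  log <- list()
  for (f in screen) {
    r_with_kept <- if (length(kept) > 0)
      vapply(kept, function(k)
        cor(ct$data[[f]], ct$data[[k]], use = "pairwise.complete.obs"),
        numeric(1)) else numeric()
    over <- which(abs(r_with_kept) > corr_threshold)
    if (length(over) > 0) {
      partner <- kept[over[1]]
      log[[length(log) + 1]] <- data.frame(kept = partner, dropped = f,
                                           r = r_with_kept[over[1]],
                                           stringsAsFactors = FALSE)
    } else {
      kept <- c(kept, f)
    }
  }
  dropped_pairs <- if (length(log) > 0) do.call(rbind, log)
    else data.frame(kept = character(), dropped = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  ct$data[dropped_pairs$dropped] <- NULL
  list(table = refresh_features(ct), dropped_pairs = dropped_pairs)
}

#' Propensity-weighted downsampling of negative participants
#'
#' Fits a logistic propensity model P(y = 1 | age, sex, BMI) and resamples
#' the negatives without replacement with probability proportional to their
#' predicted propensity, down to `ipw_ratio` negatives per positive.
#' Positives are never touched. Because negatives resembling the cases (in
#' the baseline covariates) are preferentially retained, baseline
#' confounding of downstream feature scores is reduced. When the negatives
#' already number at most `ipw_ratio` per positive the table is returned
#' unchanged.
#'
#' @param ct `cohort_table` with the baseline covariates present.
#' @param ipw_ratio Target negatives-per-positive ratio (default 9).
#' @param seed Integer seed; the draw is deterministic.
#' @return Downsampled `cohort_table` (attribute `ipw_noop` is TRUE when no
#'   resampling was needed).
#' @export
ipw_downsample <- function(ct, ipw_ratio = 9, seed = 1L) {
  stopifnot(inherits(ct, "cohort_table"), ipw_ratio >= 1)
  y <- ct$data[[ct$target]]
  n_pos <- sum(y == 1)
  if (n_pos < 1) stop("ipw_downsample: no positive participants")
  neg_idx <- which(y == 0)
  n_keep <- floor(ipw_ratio * n_pos)
  if (length(neg_idx) <= n_keep) {
    attr(ct, "ipw_noop") <- TRUE
    return(ct)
  }
  fml <- stats::as.formula(paste(ct$target, "~",
                                 paste(ct$covariates, collapse = " + ")))
  fit <- glm(fml, data = ct$data, family = binomial())
  prop <- predict(fit, type = "response")[neg_idx]
  prop <- pmax(prop, .Machine$double.eps)
  keep <- with_seed(seed, sample(neg_idx, n_keep, replace = FALSE, prob = prop))
  ct$data <- ct$data[sort(c(which(y == 1), keep)), , drop = FALSE]
  rownames(ct$data) <- NULL
  attr(ct, "ipw_noop") <- FALSE
  ct
}

#' Full cohort preparation pass
#'
#' Applies, in order: sparse-feature removal, mean imputation with
#' missingness flags, correlation deduplication, and (optionally)
#' propensity-weighted negative downsampling. The order matters: imputation
#' needs observed means, and the correlation screen needs complete columns.
#' The pass is idempotent — running it on its own output changes nothing.
#'
#' @param ct `cohort_table`.
#' @param config `prep_config`.
#' @return List: `table` (prepared `cohort_table`) and `log` (data frame of
#'   dropped features with reasons).
#' @export
prep_cohort <- function(ct, config = prep_config()) {
  stopifnot(inherits(ct, "cohort_table"), inherits(config, "prep_config"))
  sp <- drop_sparse_features(ct, config$min_nonmissing)
  log <- if (length(sp$dropped) > 0)
    data.frame(feature = sp$dropped, reason = "sparse", detail = "",
               stringsAsFactors = FALSE)
  else data.frame(feature = character(), reason = character(),
                  detail = character(), stringsAsFactors = FALSE)
  ct <- impute_and_flag(sp$table)
  dc <- drop_correlated(ct, config$corr_threshold)
  if (nrow(dc$dropped_pairs) > 0)
    log <- rbind(log, data.frame(
      feature = dc$dropped_pairs$dropped, reason = "correlated",
      detail = paste0("kept=", dc$dropped_pairs$kept,
                      " r=", signif(dc$dropped_pairs$r, 3)),
      stringsAsFactors = FALSE))
  ct <- dc$table
  if (config$ipw_enabled)
    ct <- ipw_downsample(ct, config$ipw_ratio, config$seed)
  list(table = ct, log = log)
}
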