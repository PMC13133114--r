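#' Full screening configuration
#'
#' Bundles the per-stage configurations and toggles for the screening
#' cascade. All randomness flows from the single top-level `seed`, from
#' which each stochastic stage derives its own sub-seed.
#'
#' @param prep [prep_config()].
#' @param utility [utility_config()].
#' @param link List: `max_entities`, `min_score`, `low_sim`, `theta_sim`,
#'   `exclude_patterns` (character vector of case-insensitive regexes over
#'   entity categories/names).
#' @param lit [lit_config()].
#' @param llm List: `max_retries`, `top_k`, `min_interestingness`
#'   (exclusive cutoff).
#' @param rag List: `enabled`, `k`.
#' @param stages Named logical toggles: `kg`, `literature`, `llm` (a
#'   disabled stage passes every candidate through unchanged).
#' @param seed Top-level integer seed.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(prep = prep_config(), utility = utility_config(),
                          link = list(max_entities = 3L, min_score = 0.88,
                                      low_sim = 0.1, theta_sim = 0.4,
                                      exclude_patterns = character()),
                          lit = lit_config(),
                          llm = list(max_retries = 2L, top_k = 30L,
                                     min_interestingness = 2),
                          rag = list(enabled = TRUE, k = 32L),
                          stages = c(kg = TRUE, literature = TRUE, llm = TRUE),
                          seed = 1L) {
  for (p in link$exclude_patterns)
    tryCatch(grepl(p, ""), error = function(e)
      stop("screen_config: invalid exclude pattern: ", p))
  prep$seed <- as.integer(seed) + 1L
  utility$seed <- as.integer(seed) + 2L
  structure(list(prep = prep, utility = utility, link = link, lit = lit,
                 llm = llm, rag = rag, stages = stages,
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Screen a cohort for novel, plausible, useful feature-target hypotheses
#'
#' Runs the full cascade: cohort preparation (sparse-feature removal, mean
#' imputation with missingness flags, correlation deduplication, optional
#' propensity-weighted negative downsampling), three-criterion utility
#' scoring, entity linking, knowledge-graph 1-hop novelty screening,
#' literature co-mention screening, and language-model annotation with
#' final ranked selection. Returns a classed object carrying the per-stage
#' verdicts and the funnel of surviving-feature counts.
#'
#' @param cohort A [cohort_table()] (or a plain data frame with a `target`
#'   column and `age`/`sex`/`bmi` covariates).
#' @param target_name Human-readable target (disease) name, used for
#'   literature queries and prompts.
#' @param target_entities Character vector of target entity ids in the
#'   knowledge graph.
#' @param kg A `knowledge_graph` from [load_kg()], or NULL to skip the KG
#'   stage.
#' @param link_provider Concept-linking provider, e.g. [lexicon_provider()];
#'   NULL skips linking (every feature treated as unlinked).
#' @param lit_provider Literature count provider, e.g.
#'   [lit_count_provider()]; NULL skips the literature stage.
#' @param llm_provider Annotation provider, e.g. [scripted_llm_provider()];
#'   NULL skips annotation (all post-literature candidates are kept,
#'   unranked).
#' @param corpus Optional retrieval corpus (`bm25_index` or character
#'   vector) for annotation context.
#' @param config A [screen_config()].
#' @return Object of class `feature_screen`; see [print.feature_screen()]
#'   and [summary.feature_screen()]. Components include `funnel`, `scores`,
#'   `links`, `kg_verdicts`, `lit_verdicts`, `annotations`, `selected`,
#'   `prep_log`, `config`.
#' @export
feature_screen <- function(cohort, target_name = "target disease",
                           target_entities = character(), kg = NULL,
                           link_provider = NULL, lit_provider = NULL,
                           llm_provider = NULL, corpus = NULL,
                           config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (!inherits(cohort, "cohort_table")) cohort <- cohort_table(cohort)
  use_kg <- isTRUE(config$stages[["kg"]]) && !is.null(kg) &&
    !is.null(link_provider) && length(target_entities) > 0
  use_lit <- isTRUE(config$stages[["literature"]]) && !is.null(lit_provider)
  use_llm <- isTRUE(config$stages[["llm"]]) && !is.null(llm_provider)

  prep <- prep_cohort(cohort, config$prep)
  ct <- prep$table
  scores <- utility_scores(ct, config$utility)
  passed <- scores$feature[scores$pass_utility]

  feature_text <- function(f) {
    i <- match(f, ct$meta$feature)
    if (is.na(i)) gsub("[._]+", " ", f)
    else trimws(paste(ct$meta$name[i], ct$meta$description[i]))
  }

  links <- list()
  kg_verdicts <- list()
  kg_pass <- passed
  if (use_kg) {
    lk <- config$link
    for (f in passed) {
      l <- link_feature(feature_text(f), link_provider,
                        max_entities = lk$max_entities,
                        min_link_score = lk$min_score)
      l <- exclude_categories(l, lk$exclude_patterns)
      l <- similarity_gate(l, link_provider, low_sim = lk$low_sim,
                           theta_sim = lk$theta_sim)
      links[[f]] <- l
      kg_verdicts[[f]] <- is_known(l, target_entities, kg,
                                   theta_sim = lk$theta_sim)
    }
    kg_pass <- passed[!vapply(kg_verdicts[passed], `[[`, logical(1), "known")]
  }

  lit_verdicts <- list()
  lit_pass <- kg_pass
  if (use_lit) {
    for (f in kg_pass) {
      i <- match(f, ct$meta$feature)
      term <- if (is.na(i)) gsub("[._]+", " ", f) else ct$meta$name[i]
      lit_verdicts[[f]] <- literature_filter(
        pair_counts(lit_provider, term, target_name), config$lit)
    }
    lit_pass <- kg_pass[vapply(lit_verdicts[kg_pass], `[[`, logical(1),
                               "retain")]
  }

  cand <- data.frame(
    id = lit_pass,
    feature_name = vapply(lit_pass, function(f) {
      i <- match(f, ct$meta$feature)
      if (is.na(i)) gsub("[._]+", " ", f) else ct$meta$name[i]
    }, character(1)),
    target_name = rep(target_name, length(lit_pass)),
    direction = scores$direction[match(lit_pass, scores$feature)],
    fimp = scores$fimp[match(lit_pass, scores$feature)],
    pval = scores$pval[match(lit_pass, scores$feature)],
    mi = scores$mi[match(lit_pass, scores$feature)],
    stringsAsFactors = FALSE, row.names = NULL)

  annotations <- NULL
  selected <- cand
  if (use_llm && nrow(cand) > 0) {
    cand$statistics <- sprintf("pval=%.3g, mi=%.3g, fimp=%.3g, direction=%s",
                               cand$pval, cand$mi, cand$fimp, cand$direction)
    rag_corpus <- if (isTRUE(config$rag$enabled)) corpus else NULL
    annotations <- annotate_candidates(cand, llm_provider,
                                       corpus = rag_corpus,
                                       k = config$rag$k %||% 32L,
                                       max_retries = config$llm$max_retries %||% 2L)
    selected <- select_candidates(
      annotations,
      min_interestingness_exclusive = config$llm$min_interestingness %||% 2,
      top_k = config$llm$top_k %||% 30L)
  } else if (nrow(selected) > 0) {
    selected$rank <- order(order(-selected$fimp, selected$id))
    selected <- selected[order(selected$rank), , drop = FALSE]
    rownames(selected) <- NULL
  }

  funnel <- data.frame(
    stage = c("prepared", "utility", "kg", "literature", "selected"),
    count = c(length(ct$features), length(passed), length(kg_pass),
              length(lit_pass), nrow(selected)),
    stringsAsFactors = FALSE)

  structure(list(funnel = funnel, scores = scores, links = links,
                 kg_verdicts = kg_verdicts, lit_verdicts = lit_verdicts,
                 annotations = annotations, selected = selected,
                 prep_log = prep$log, table = ct,
                 target_name = target_name,
                 target_entities = target_entities, config = config),
            class = "feature_screen")
}

#' @rdname feature_screen
#' @param x,object A `feature_screen` object.
#' @param ... Unused.
#' @export
print.feature_screen <- function(x, ...) {
  cat("Feature screen for \"", x$target_name, "\"\n", sep = "")
  cat("Funnel (features surviving each stage):\n")
  for (i in seq_len(nrow(x$funnel)))
    cat(sprintf("  %-10s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  if (nrow(x$selected) > 0) {
    cat("Top candidates:\n")
    top <- head(x$selected, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %2d. %s (%s%s)\n", i, top$feature_name[i],
                  top$direction[i],
                  if (!is.null(top$interestingness))
                    paste0(", interestingness ", top$interestingness[i])
                  else ""))
  } else cat("No candidates selected.\n")
  invisible(x)
}

#' @rdname feature_screen
#' @export
summary.feature_screen <- function(object, ...) {
  reasons_kg <- table(vapply(object$kg_verdicts, `[[`, character(1), "reason"))
  reasons_lit <- table(vapply(object$lit_verdicts, `[[`, character(1),
                              "reason"))
  out <- list(funnel = object$funnel,
              kg_reasons = reasons_kg, lit_reasons = reasons_lit,
              n_selected = nrow(object$selected),
              selected = object$selected)
  class(out) <- "summary.feature_screen"
  out
}

#' @export
print.summary.feature_screen <- function(x, ...) {
  cat("Funnel:\n"); print(x$funnel)
  if (length(x$kg_reasons)) { cat("KG verdicts:\n"); print(x$kg_reasons) }
  if (length(x$lit_reasons)) {
    cat("Literature verdicts:\n"); print(x$lit_reasons)
  }
  invisible(x)
}

#' Write screening outputs to disk
#'
#' Writes `selected.csv` (ranked candidates), `funnel.csv` (per-stage
#' counts) and `run_meta.json` (seed, configuration hash, package version)
#' into a directory, so runs are auditable and reproducible.
#'
#' @param screen A `feature_screen` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
screen_write <- function(screen, dir) {
  stopifnot(inherits(screen, "feature_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel <- screen$selected
  sel <- sel[, setdiff(names(sel), "statistics"), drop = FALSE]
  write.csv(sel, file.path(dir, "selected.csv"), row.names = FALSE)
  write.csv(screen$funnel, file.path(dir, "funnel.csv"), row.names = FALSE)
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(screen$config, cfg_file, version = 2)
  meta <- list(seed = screen$config$seed,
               config_hash = unname(tools::md5sum(cfg_file)),
               package_version = as.character(utils::packageVersion("novelfeat")),
               target = screen$target_name)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
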