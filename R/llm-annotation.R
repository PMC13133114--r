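# Candidate annotation through a pluggable language-model provider.
#
# Candidates surviving the utility and novelty screens are scored 1-4 for
# novelty, plausibility and overall interestingness, with free-text
# rationales, optionally grounded in BM25-retrieved corpus snippets.
# Providers expose a single `complete(prompt)` function; the bundled
# scripted provider makes the stage deterministic and offline.

#' Build a BM25 index over a document corpus
#'
#' Okapi BM25 with the usual defaults (k1 = 1.5, b = 0.75) and
#' idf = log(1 + (N - df + 0.5) / (df + 0.5)).
#'
#' @param docs Character vector of document texts; names are used as
#'   document ids (defaults to doc_1, doc_2, ...).
#' @param k1,b BM25 parameters.
#' @return Object of class `bm25_index`.
#' @export
bm25_index <- function(docs, k1 = 1.5, b = 0.75) {
  ids <- names(docs) %||% sprintf("doc_%d", seq_along(docs))
  docs <- setNames(as.character(docs), ids)
  toks <- lapply(docs, tokenize)
  lens <- vapply(toks, length, integer(1))
  tf <- lapply(toks, function(t) table(t))
  df <- table(unlist(lapply(toks, unique)))
  structure(list(ids = ids, docs = docs, tf = tf, df = df,
                 lens = lens, avgdl = mean(pmax(lens, 1)),
                 n_docs = length(docs), k1 = k1, b = b),
            class = "bm25_index")
}

bm25_scores <- function(index, query) {
  q <- unique(tokenize(query))
  scores <- numeric(index$n_docs)
  for (term in q) {
    dfi <- index$df[term]
    if (is.na(dfi)) next
    idf <- log(1 + (index$n_docs - dfi + 0.5) / (dfi + 0.5))
    for (i in seq_len(index$n_docs)) {
      f <- index$tf[[i]][term]
      if (is.na(f)) next
      denom <- f + index$k1 * (1 - index$b +
                                 index$b * index$lens[i] / index$avgdl)
      scores[i] <- scores[i] + idf * f * (index$k1 + 1) / denom
    }
  }
  scores
}

#' Retrieve supporting context for a candidate hypothesis
#'
#' Ranks the corpus by BM25 score for the combined feature + target query
#' and returns the top k documents (ties broken by corpus order, so the
#' ranking is deterministic). An empty corpus yields an empty context and
#' annotation proceeds without retrieval.
#'
#' @param candidate List with `feature_name` and `target_name` (a plain
#'   query string is also accepted).
#' @param corpus A `bm25_index`, or a character vector of documents.
#' @param k Number of documents to return, default 32.
#' @return Data frame `doc_id`, `score`, `text`, best first.
#' @export
retrieve_context <- function(candidate, corpus, k = 32L) {
  query <- if (is.character(candidate)) candidate
    else paste(candidate$feature_name, candidate$target_name)
  if (is.null(corpus) ||
      (!inherits(corpus, "bm25_index") && length(corpus) == 0))
    return(data.frame(doc_id = character(), score = numeric(),
                      text = character(), stringsAsFactors = FALSE))
  if (!inherits(corpus, "bm25_index")) corpus <- bm25_index(corpus)
  s <- bm25_scores(corpus, query)
  ord <- order(-s, seq_along(s))
  ord <- head(ord, k)
  data.frame(doc_id = corpus$ids[ord], score = s[ord],
             text = unname(corpus$docs[ord]), stringsAsFactors = FALSE)
}

#' Default chain-of-thought annotation prompt template
#'
#' The template asks the model to reason step by step about the candidate
#' association, then give separate 1-4 judgments for novelty, plausibility
#' and overall interestingness in a machine-parseable answer block. Slots:
#' `{{candidate_id}}`, `{{feature}}`, `{{target}}`, `{{direction}}`,
#' `{{statistics}}`, `{{context}}`.
#'
#' @return Template string.
#' @export
default_prompt_template <- function() {
  paste0(
    "You are screening candidate risk-factor hypotheses in cohort data.\n",
    "CANDIDATE-ID: {{candidate_id}}\n",
    "Hypothesis: the feature \"{{feature}}\" is related to \"{{target}}\" ",
    "with a {{direction}} correlation.\n",
    "Feature statistics: {{statistics}}\n",
    "{{context}}",
    "Think step by step about what is already established, what mechanism ",
    "could explain the association, and whether the direction is expected.\n",
    "Then answer with integer scores from 1 (lowest) to 4 (highest) in ",
    "exactly this format:\n",
    "ANSWER\nNOVELTY: <1-4>\nPLAUSIBILITY: <1-4>\n",
    "INTERESTINGNESS: <1-4>\nEXPLANATION: <one paragraph>\nEND ANSWER\n")
}

#' Distractor-justification prompt template
#'
#' Variant used when constructing distractor candidates for annotator
#' studies: asks the model to argue why the (discarded) feature would be
#' interesting, so distractors carry justifications comparable to real
#' candidates.
#'
#' @return Template string.
#' @export
distractor_prompt_template <- function() {
  paste0(
    "CANDIDATE-ID: {{candidate_id}}\n",
    "Write a persuasive justification for why the feature \"{{feature}}\" ",
    "would be an interesting {{direction}} risk factor for \"{{target}}\".\n",
    "Feature statistics: {{statistics}}\n",
    "{{context}}",
    "Answer in the format:\nANSWER\nNOVELTY: <1-4>\nPLAUSIBILITY: <1-4>\n",
    "INTERESTINGNESS: <1-4>\nEXPLANATION: <why this is interesting>\n",
    "END ANSWER\n")
}

#' Fill an annotation prompt template for a candidate
#'
#' @param candidate List with `id`, `feature_name`, `target_name`,
#'   `direction`, and optionally `statistics` (named vector or string).
#' @param context_docs Data frame from [retrieve_context()], or NULL; when
#'   empty the context section is omitted.
#' @param template Template string with `{{slot}}` markers.
#' @return Prompt text; unfilled slots are an error.
#' @export
build_prompt <- function(candidate, context_docs = NULL,
                         template = default_prompt_template()) {
  stats_txt <- candidate$statistics %||% "not available"
  if (!is.character(stats_txt) || length(stats_txt) > 1)
    stats_txt <- paste(names(stats_txt), signif(unlist(stats_txt), 3),
                       sep = "=", collapse = ", ")
  ctx_txt <- if (!is.null(context_docs) && nrow(context_docs) > 0)
    paste0("Retrieved context:\n",
           paste0("- [", context_docs$doc_id, "] ", context_docs$text,
                  collapse = "\n"), "\n")
  else ""
  fill <- c(candidate_id = as.character(candidate$id),
            feature = as.character(candidate$feature_name),
            target = as.character(candidate$target_name),
            direction = as.character(candidate$direction),
            statistics = stats_txt, context = ctx_txt)
  if (any(is.na(fill) | (names(fill) != "context" & !nzchar(fill))))
    stop("build_prompt: empty slot value(s): ",
         paste(names(fill)[is.na(fill) | !nzchar(fill)], collapse = ", "))
  out <- template
  for (slot in names(fill))
    out <- gsub(paste0("{{", slot, "}}"), fill[[slot]], out, fixed = TRUE)
  leftover <- regmatches(out, gregexpr("\\{\\{[a-z_]+\\}\\}", out))[[1]]
  if (length(leftover) > 0)
    stop("build_prompt: unfilled slot(s): ", paste(leftover, collapse = ", "))
  out
}

#' Parse a structured annotation from raw model output
#'
#' Extracts the three integer scores and the explanation from the answer
#' block, validating that each score is in 1..4. Malformed output raises a
#' condition of class `annotation_parse_error` so callers can retry.
#'
#' @param raw_text Raw completion text.
#' @return List of class `llm_annotation`: `novelty`, `plausibility`,
#'   `interestingness`, `confidence` (the ranking key; equal to the overall
#'   interestingness score by default), `explanation`.
#' @export
parse_annotation <- function(raw_text) {
  grab <- function(label) {
    m <- regmatches(raw_text,
                    regexec(paste0(label, ":\\s*(-?[0-9]+)"), raw_text))[[1]]
    if (length(m) < 2)
      stop(structure(class = c("annotation_parse_error", "error", "condition"),
                     list(message = paste0("parse_annotation: missing ",
                                           label, " score"),
                          call = sys.call(-1))))
    as.integer(m[2])
  }
  nov <- grab("NOVELTY"); pla <- grab("PLAUSIBILITY")
  int <- grab("INTERESTINGNESS")
  if (!all(c(nov, pla, int) %in% 1:4))
    stop(structure(class = c("annotation_parse_error", "error", "condition"),
                   list(message = "parse_annotation: score outside 1-4",
                        call = sys.call(-1))))
  ex <- regmatches(raw_text,
                   regexec("EXPLANATION:\\s*([^\n]*)", raw_text))[[1]]
  structure(list(novelty = nov, plausibility = pla, interestingness = int,
                 confidence = int,
                 explanation = if (length(ex) >= 2) ex[2] else ""),
            class = "llm_annotation")
}

#' Binarize a 1-4 annotation score
#'
#' @param score Integer score in 1..4.
#' @return TRUE iff score > 2.
#' @export
binarize <- function(score) {
  if (!all(score %in% 1:4)) stop("binarize: score outside 1-4")
  score > 2
}

#' Annotate a set of candidates through a provider
#'
#' For each candidate: retrieve context (if a corpus is given), build the
#' prompt, call the provider and parse the structured answer. Unparseable
#' completions are retried up to `max_retries` times, after which the
#' candidate is flagged unannotated (NA scores) rather than dropped
#' silently.
#'
#' @param candidates Data frame with columns `id`, `feature_name`,
#'   `target_name`, `direction`, and optionally `fimp`.
#' @param provider Provider with `complete(prompt)`.
#' @param corpus Optional `bm25_index` or character corpus for retrieval.
#' @param k Retrieved documents per candidate, default 32.
#' @param template Prompt template.
#' @param max_retries Parse-failure retries per candidate, default 2.
#' @return Data frame: candidate columns plus `novelty`, `plausibility`,
#'   `interestingness`, `confidence`, `explanation`, `annotated`.
#' @export
annotate_candidates <- function(candidates, provider, corpus = NULL,
                                k = 32L, template = default_prompt_template(),
                                max_retries = 2L) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "feature_name", "target_name", "direction") %in%
                  names(candidates)))
  out <- candidates
  out$novelty <- out$plausibility <- out$interestingness <- NA_integer_
  out$confidence <- NA_real_
  out$explanation <- NA_character_
  out$annotated <- FALSE
  for (i in seq_len(nrow(candidates))) {
    cand <- as.list(candidates[i, , drop = FALSE])
    ctx <- if (!is.null(corpus)) retrieve_context(
      list(feature_name = cand$feature_name, target_name = cand$target_name),
      corpus, k) else NULL
    prompt <- build_prompt(cand, ctx, template)
    ann <- NULL
    for (attempt in seq_len(max_retries + 1L)) {
      ann <- tryCatch(parse_annotation(provider$complete(prompt)),
                      annotation_parse_error = function(e) NULL)
      if (!is.null(ann)) break
    }
    if (!is.null(ann)) {
      out$novelty[i] <- ann$novelty
      out$plausibility[i] <- ann$plausibility
      out$interestingness[i] <- ann$interestingness
      out$confidence[i] <- ann$confidence
      out$explanation[i] <- ann$explanation
      out$annotated[i] <- TRUE
    }
  }
  out
}

#' Select and rank the final candidate hypotheses
#'
#' Keeps candidates whose overall interestingness exceeds the cutoff
#' (strictly), sorts by confidence descending with ties broken by model
#' importance (`fimp`) descending and then feature id, and truncates to the
#' top k for expert review.
#'
#' @param annotations Data frame from [annotate_candidates()].
#' @param min_interestingness_exclusive Keep scores strictly above this
#'   (default 2).
#' @param top_k Maximum candidates returned, default 30.
#' @return Ranked data frame with a `rank` column (possibly empty).
#' @export
select_candidates <- function(annotations, min_interestingness_exclusive = 2,
                              top_k = 30L) {
  stopifnot(is.data.frame(annotations),
            all(c("id", "interestingness", "confidence") %in%
                  names(annotations)))
  keep <- annotations[!is.na(annotations$interestingness) &
                        annotations$interestingness >
                          min_interestingness_exclusive, , drop = FALSE]
  if (nrow(keep) == 0) {
    keep$rank <- integer(0)
    return(keep)
  }
  fimp <- keep$fimp %||% rep(0, nrow(keep))
  ord <- order(-keep$confidence, -fimp, keep$id)
  keep <- keep[ord, , drop = FALSE]
  keep <- head(keep, top_k)
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}
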