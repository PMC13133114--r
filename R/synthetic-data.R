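# Synthetic study-condition generators.
#
# Every pipeline input (cohort, knowledge graph, literature counts, language
# model, retrieval corpus) can be generated with planted ground truth so the
# whole cascade is testable offline. The generators are deterministic under
# the spec seed.

#' Specification for a synthetic cohort
#'
#' Describes a case-control cohort with planted risk factors: the binary
#' outcome is drawn from a logistic model over the planted features
#' (standardized, with stated log-odds-per-SD effects) and the baseline
#' covariates (age, sex, BMI) with stated confounder strengths; all other
#' features are independent noise. Per-feature flags declare whether the
#' planted association is already present in the knowledge graph
#' (`kg_known`) or established in the literature (`lit_known`) — the ground
#' truth the novelty stages are judged against.
#'
#' @param n_patients Number of participants.
#' @param n_features Number of null (noise) features; planted features are
#'   additional named columns.
#' @param prevalence Target outcome prevalence in (0, 1).
#' @param planted Data frame with columns `feature` (id), `effect`
#'   (log-odds per SD; sign is the effect direction), `kg_known`,
#'   `lit_known` (logicals). May be NULL/empty.
#' @param confounders Data frame with columns `covariate` (one of `age`,
#'   `sex`, `bmi`) and `strength` (log-odds per SD). May be NULL.
#' @param missing_rate Fraction of feature values set missing completely at
#'   random.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients, n_features, prevalence,
                           planted = NULL, confounders = NULL,
                           missing_rate = 0, seed = 1L) {
  if (is.null(planted) || nrow(planted) == 0)
    planted <- data.frame(feature = character(), effect = numeric(),
                          kg_known = logical(), lit_known = logical(),
                          stringsAsFactors = FALSE)
  if (is.null(confounders))
    confounders <- data.frame(covariate = character(), strength = numeric(),
                              stringsAsFactors = FALSE)
  stopifnot(n_patients >= 1, n_features >= 0,
            prevalence > 0, prevalence < 1,
            all(c("feature", "effect", "kg_known", "lit_known") %in%
                  names(planted)),
            all(is.finite(planted$effect)),
            missing_rate >= 0, missing_rate < 1)
  if (anyDuplicated(planted$feature))
    stop("synthetic_spec: duplicate planted feature ids")
  if (nrow(confounders) > 0 &&
      !all(confounders$covariate %in% c("age", "sex", "bmi")))
    stop("synthetic_spec: confounder covariates must be age/sex/bmi")
  if (n_patients * prevalence < 10)
    stop("synthetic_spec: expected cases < 10; enlarge the cohort")
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 prevalence = prevalence, planted = planted,
                 confounders = confounders, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort with planted risk factors
#'
#' Draws baseline covariates (age ~ N(57, 8), sex ~ Bernoulli(0.5),
#' BMI ~ N(27, 4)), independent standard-normal features, and a binary
#' outcome from the logistic model described in [synthetic_spec()]. The
#' intercept is calibrated numerically so the expected prevalence matches
#' the spec. Missingness is injected completely at random into feature
#' columns. Byte-identical under a fixed seed.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `cohort` (a [cohort_table()]) and `truth` (data frame
#'   `feature`, `planted`, `effect`, `kg_known`, `lit_known`,
#'   `expected_final_candidate`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    age <- rnorm(n, 57, 8)
    sex <- rbinom(n, 1, 0.5)
    bmi <- rnorm(n, 27, 4)
    null_ids <- if (spec$n_features > 0)
      sprintf("feat_%03d", seq_len(spec$n_features)) else character()
    planted_ids <- spec$planted$feature
    if (any(planted_ids %in% null_ids))
      stop("generate_cohort: planted ids collide with null feature ids")
    feats <- matrix(rnorm(n * (length(null_ids) + length(planted_ids))), n)
    colnames(feats) <- c(null_ids, planted_ids)
    zscale <- function(v) (v - mean(v)) / sd(v)
    eta <- rep(0, n)
    for (i in seq_len(nrow(spec$planted)))
      eta <- eta + spec$planted$effect[i] * zscale(feats[, planted_ids[i]])
    covs <- list(age = age, sex = sex, bmi = bmi)
    for (i in seq_len(nrow(spec$confounders)))
      eta <- eta + spec$confounders$strength[i] *
        zscale(covs[[spec$confounders$covariate[i]]])
    b0 <- uniroot(function(b) mean(plogis(b + eta)) - spec$prevalence,
                  interval = c(-30, 30))$root
    y <- rbinom(n, 1, plogis(b0 + eta))
    if (spec$missing_rate > 0) {
      mask <- matrix(runif(length(feats)) < spec$missing_rate,
                     nrow(feats))
      feats[mask] <- NA_real_
    }
    dat <- data.frame(target = y, age = age, sex = sex, bmi = bmi,
                      feats, check.names = FALSE)
    truth <- data.frame(
      feature = c(null_ids, planted_ids),
      planted = c(rep(FALSE, length(null_ids)), rep(TRUE, length(planted_ids))),
      effect = c(rep(0, length(null_ids)), spec$planted$effect),
      kg_known = c(rep(FALSE, length(null_ids)), spec$planted$kg_known),
      lit_known = c(rep(FALSE, length(null_ids)), spec$planted$lit_known),
      stringsAsFactors = FALSE)
    truth$expected_final_candidate <- truth$planted & !truth$kg_known &
      !truth$lit_known
    list(cohort = cohort_table(dat), truth = truth)
  })
}

#' Write a toy knowledge-graph triple file
#'
#' Emits a SemMed-style CSV (`subject_cui,predicate,object_cui,n_citations,
#' first_year`) containing every requested known pair with its citation
#' count and first-report year, plus random background edges between other
#' entities. Deterministic under the seed.
#'
#' @param entities Character vector of entity ids (unique).
#' @param known_pairs Data frame with columns `a`, `b`, `n_citations`,
#'   `first_year`; may be empty.
#' @param path Output CSV path (default: a tempfile).
#' @param n_background Number of random background edges, default 30.
#' @param seed Integer seed.
#' @return The path, invisibly usable by [load_kg()].
#' @export
generate_toy_kg <- function(entities, known_pairs = NULL,
                            path = tempfile(fileext = ".csv"),
                            n_background = 30L, seed = 1L) {
  if (anyDuplicated(entities)) stop("generate_toy_kg: duplicate entity ids")
  if (is.null(known_pairs))
    known_pairs <- data.frame(a = character(), b = character(),
                              n_citations = numeric(), first_year = numeric(),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "n_citations", "first_year") %in%
                  names(known_pairs)))
  if (nrow(known_pairs) > 0) {
    key <- edge_key(known_pairs$a, known_pairs$b)
    if (any(tapply(known_pairs$first_year, key,
                   function(v) length(unique(v))) > 1))
      stop("generate_toy_kg: duplicate pair with conflicting first_year")
  }
  with_seed(seed, {
    rows <- known_pairs
    names(rows)[match(c("a", "b"), names(rows))] <- c("subject_cui", "object_cui")
    rows$predicate <- rep("ASSOCIATED_WITH", nrow(rows))
    if (n_background > 0 && length(entities) >= 2) {
      known_keys <- if (nrow(known_pairs) > 0)
        edge_key(known_pairs$a, known_pairs$b) else character()
      bg <- list()
      tries <- 0
      while (length(bg) < n_background && tries < 50 * n_background) {
        tries <- tries + 1
        pair <- sample(entities, 2)
        k <- edge_key(pair[1], pair[2])
        if (k %in% known_keys || k %in% names(bg)) next
        bg[[k]] <- data.frame(subject_cui = pair[1], object_cui = pair[2],
                              n_citations = sample(1:5, 1),
                              first_year = sample(1990:2020, 1),
                              predicate = "ASSOCIATED_WITH",
                              stringsAsFactors = FALSE)
      }
      if (length(bg) > 0) rows <- rbind(rows, do.call(rbind, bg))
    }
    rows <- rows[, c("subject_cui", "predicate", "object_cui",
                     "n_citations", "first_year")]
    rownames(rows) <- NULL
    write.csv(rows, path, row.names = FALSE)
  })
  invisible(path)
}

#' Build a deterministic literature count table
#'
#' Offline stand-in for a live publication-count service: term and pair
#' counts are taken from the given tables; anything absent counts 0.
#'
#' @param terms Named numeric vector: term -> hit count.
#' @param pair_overrides Data frame `term_a`, `term_b`, `pair_count`
#'   (or NULL).
#' @param corpus_size Document universe size; must be at least the largest
#'   term count.
#' @return A count provider (see [lit_count_provider()]).
#' @export
generate_literature_counts <- function(terms, pair_overrides = NULL,
                                       corpus_size = 37e6) {
  if (length(terms) > 0 && corpus_size < max(terms))
    stop("generate_literature_counts: corpus smaller than a term count")
  lit_count_provider(terms, pair_overrides, corpus_size)
}

#' Scripted language-model provider
#'
#' Deterministic test double for the annotation stage: a map from candidate
#' id to scripted novelty/plausibility/interestingness scores (1-4) and an
#' explanation. The provider answers `complete(prompt)` by locating the
#' candidate id marker in the prompt and emitting a structured answer block
#' that [parse_annotation()] can read.
#'
#' @param script Named list: candidate id -> list with `novelty`,
#'   `plausibility`, `interestingness` (each in 1..4) and optional
#'   `explanation`. Entries may also be length-3 numeric vectors.
#' @param default Optional default scores (same format, without id) for
#'   candidates missing from the script; if NULL, unknown candidates are an
#'   error.
#' @param malform Candidate ids for which the provider should return
#'   unparseable text (exercises the parser's failure path).
#' @return Provider: list with `complete(prompt)`.
#' @export
scripted_llm_provider <- function(script = list(), default = NULL,
                                  malform = character()) {
  canon <- function(s, id) {
    if (is.numeric(s) && length(s) == 3)
      s <- list(novelty = s[1], plausibility = s[2], interestingness = s[3])
    need <- c("novelty", "plausibility", "interestingness")
    if (!all(need %in% names(s)))
      stop("scripted_llm_provider: entry '", id, "' lacks ",
           paste(setdiff(need, names(s)), collapse = ","))
    sc <- unlist(s[need])
    if (!all(sc %in% 1:4))
      stop("scripted_llm_provider: scores must be in 1..4 (entry '", id, "')")
    s$explanation <- s$explanation %||%
      paste0("Scripted rationale for ", id, ".")
    s
  }
  script <- if (length(script) > 0)
    setNames(lapply(names(script), function(id) canon(script[[id]], id)),
             names(script)) else list()
  if (!is.null(default)) default <- canon(default, "<default>")
  list(complete = function(prompt) {
    m <- regmatches(prompt, regexec("CANDIDATE-ID: ([^\n]+)", prompt))[[1]]
    if (length(m) < 2) stop("scripted_llm_provider: no candidate id in prompt")
    id <- trimws(m[2])
    if (id %in% malform) return("I am not sure what to answer here.")
    s <- script[[id]] %||% default
    if (is.null(s))
      stop("scripted_llm_provider: unscripted candidate '", id, "'")
    paste0("Reasoning: considered prior evidence for ", id, ".\n",
           "ANSWER\n",
           "NOVELTY: ", s$novelty, "\n",
           "PLAUSIBILITY: ", s$plausibility, "\n",
           "INTERESTINGNESS: ", s$interestingness, "\n",
           "EXPLANATION: ", s$explanation, "\n",
           "END ANSWER\n")
  })
}

#' Generate a complete synthetic screening world
#'
#' Wires all the generators together: a cohort with planted features, an
#' entity lexicon holding one concept per planted feature plus the target
#' and background concepts, a toy knowledge graph in which every
#' `kg_known` planted feature has a cited edge to the target, a literature
#' count table in which every `lit_known` planted feature is heavily
#' co-mentioned with the target, a small retrieval corpus, and a scripted
#' annotation provider. The result is everything [feature_screen()] needs,
#' with ground truth attached.
#'
#' @param spec A [synthetic_spec()].
#' @param target_name Human-readable target name.
#' @param known_first_year First-report year stamped on known edges
#'   (default 2005).
#' @param default_scores Scripted annotation scores applied to every
#'   candidate, default (3, 3, 3).
#' @return List: `cohort`, `truth`, `kg`, `link_provider`, `lit_provider`,
#'   `llm_provider`, `corpus`, `target_entities`, `target_name`, `lexicon`,
#'   `kg_file`.
#' @export
generate_world <- function(spec, target_name = "gout",
                           known_first_year = 2005,
                           default_scores = c(3, 3, 3)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gen <- generate_cohort(spec)
  planted <- spec$planted
  ent_id <- function(f) paste0("C", sprintf("%07d",
                                            match(f, planted$feature)))
  target_cui <- "C9000000"
  lexicon <- data.frame(
    entity_id = c(target_cui,
                  if (nrow(planted) > 0) ent_id(planted$feature),
                  "C8000001", "C8000002", "C8000003"),
    name = c(target_name,
             if (nrow(planted) > 0) gsub("[._]+", " ", planted$feature),
             "background concept one", "background concept two",
             "background concept three"),
    category = c("Disease",
                 rep("Finding", nrow(planted)),
                 "Qualification", "Unit", "Finding"),
    stringsAsFactors = FALSE)
  known <- planted$feature[planted$kg_known]
  known_pairs <- if (length(known) > 0)
    data.frame(a = ent_id(known), b = target_cui,
               n_citations = 3, first_year = known_first_year,
               stringsAsFactors = FALSE)
  else NULL
  kg_file <- generate_toy_kg(
    setdiff(lexicon$entity_id, target_cui), known_pairs,
    n_background = 10L, seed = spec$seed + 1L)
  kg <- load_kg(kg_file, min_citations = 2L, lexicon = lexicon)
  terms <- c(setNames(5000, target_name))
  pair_overrides <- NULL
  lit_known <- planted$feature[planted$lit_known]
  if (length(lit_known) > 0) {
    nm <- gsub("[._]+", " ", lit_known)
    terms <- c(terms, setNames(rep(1000, length(nm)), nm))
    pair_overrides <- data.frame(term_a = nm, term_b = target_name,
                                 pair_count = 500, stringsAsFactors = FALSE)
  }
  lit_provider <- generate_literature_counts(terms, pair_overrides,
                                             corpus_size = 37e6)
  corpus <- c(
    doc_known = paste("Established association between",
                      paste(gsub("[._]+", " ", known), collapse = " and "),
                      "and", target_name),
    doc_target = paste("Clinical review of", target_name,
                       "risk factors and management"),
    doc_noise = "Unrelated methods paper about assay calibration")
  llm_provider <- scripted_llm_provider(default = as.list(setNames(
    as.list(default_scores),
    c("novelty", "plausibility", "interestingness"))))
  list(cohort = gen$cohort, truth = gen$truth, kg = kg,
       link_provider = lexicon_provider(lexicon),
       lit_provider = lit_provider, llm_provider = llm_provider,
       corpus = corpus, target_entities = target_cui,
       target_name = target_name, lexicon = lexicon, kg_file = kg_file)
}
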