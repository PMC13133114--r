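# Knowledge-graph novelty screen.
#
# The graph is a citation-filtered set of biomedical predications reduced to
# undirected entity adjacency: predicate type and direction are ignored, and
# an edge is trusted only when backed by a minimum number of unique
# citations. Each edge carries the calendar year it was first reported,
# which makes temporal (pre/post-cutoff) validation possible.

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

#' Load a knowledge graph from a triple file
#'
#' Reads a CSV of predications with header
#' `subject_cui,predicate,object_cui,n_citations,first_year`, drops edges
#' with fewer than `min_citations` unique citations, ignores predicate type
#' and direction, and merges parallel edges keeping the maximum evidence
#' count and the minimum (earliest) first-report year. Self-loops are
#' dropped.
#'
#' @param triple_file Path to the triple CSV.
#' @param min_citations Evidence threshold; edges below it are discarded
#'   (default 2 unique citations).
#' @param lexicon Optional entity lexicon data frame
#'   (`entity_id`, `name`, `category`); entities appearing in edges but not
#'   in the lexicon are auto-registered with an empty category (warning).
#' @return Object of class `knowledge_graph`: list with `edges`
#'   (data frame `a`, `b`, `evidence_count`, `first_year`, with `a < b`),
#'   `lexicon`, and `min_citations`.
#' @export
load_kg <- function(triple_file, min_citations = 2L, lexicon = NULL) {
  raw <- read.csv(triple_file, stringsAsFactors = FALSE)
  need <- c("subject_cui", "predicate", "object_cui", "n_citations", "first_year")
  if (!all(need %in% names(raw)))
    stop("load_kg: triple file must have columns ", paste(need, collapse = ","))
  bad <- which(is.na(raw$subject_cui) | is.na(raw$object_cui) |
                 !nzchar(raw$subject_cui) | !nzchar(raw$object_cui) |
                 is.na(suppressWarnings(as.numeric(raw$n_citations))) |
                 is.na(suppressWarnings(as.numeric(raw$first_year))))
  if (length(bad) > 0)
    stop("load_kg: malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "))
  raw$n_citations <- as.numeric(raw$n_citations)
  raw$first_year <- as.numeric(raw$first_year)
  if (any(raw$n_citations < 0)) stop("load_kg: negative citation count")
  raw <- raw[raw$subject_cui != raw$object_cui, , drop = FALSE]
  raw <- raw[raw$n_citations >= min_citations, , drop = FALSE]
  if (nrow(raw) > 0) {
    key <- edge_key(raw$subject_cui, raw$object_cui)
    ev <- tapply(raw$n_citations, key, max)
    yr <- tapply(raw$first_year, key, min)
    parts <- strsplit(names(ev), "\x1f", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[`, "", 1),
                        b = vapply(parts, `[`, "", 2),
                        evidence_count = as.numeric(ev),
                        first_year = as.numeric(yr),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(), b = character(),
                        evidence_count = numeric(), first_year = numeric(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(lexicon))
    lexicon <- data.frame(entity_id = character(), name = character(),
                          category = character(), stringsAsFactors = FALSE)
  ents <- unique(c(edges$a, edges$b))
  unknown <- setdiff(ents, lexicon$entity_id)
  if (length(unknown) > 0) {
    if (nrow(lexicon) > 0)
      warning("load_kg: auto-registering ", length(unknown),
              " entities absent from the lexicon")
    lexicon <- rbind(lexicon,
                     data.frame(entity_id = unknown, name = unknown,
                                category = "", stringsAsFactors = FALSE))
  }
  structure(list(edges = edges, lexicon = lexicon,
                 min_citations = min_citations),
            class = "knowledge_graph")
}

#' Build a knowledge graph directly from an edge data frame
#'
#' In-memory counterpart of [load_kg()] with the same merging and evidence
#' rules; convenient for tests and synthetic worlds.
#'
#' @param edges Data frame `subject_cui`, `object_cui`, `n_citations`,
#'   `first_year` (a `predicate` column is optional and ignored).
#' @inheritParams load_kg
#' @return `knowledge_graph` object.
#' @export
kg_from_edges <- function(edges, min_citations = 2L, lexicon = NULL) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  if (is.null(edges$predicate)) edges$predicate <- "ASSOCIATED_WITH"
  write.csv(edges[, c("subject_cui", "predicate", "object_cui",
                      "n_citations", "first_year")], tf, row.names = FALSE)
  load_kg(tf, min_citations = min_citations, lexicon = lexicon)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("Knowledge graph: ", nrow(x$edges), " undirected edges over ",
      length(unique(c(x$edges$a, x$edges$b))), " entities (evidence >= ",
      x$min_citations, " citations)\n", sep = "")
  invisible(x)
}

#' Test 1-hop adjacency between entities
#'
#' @param kg `knowledge_graph` object.
#' @param e1,e2 Entity id vectors (recycled pairwise).
#' @return Logical vector: is there an edge e1--e2?
#' @export
kg_adjacent <- function(kg, e1, e2) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (nrow(kg$edges) == 0) return(rep(FALSE, max(length(e1), length(e2))))
  edge_key(e1, e2) %in% edge_key(kg$edges$a, kg$edges$b)
}

# Earliest first-report year of any edge between `entity` and the targets;
# Inf when no such edge exists.
kg_first_year <- function(kg, entity, target_entities) {
  keys <- edge_key(rep(entity, length(target_entities)), target_entities)
  hit <- match(keys, edge_key(kg$edges$a, kg$edges$b))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) return(Inf)
  min(kg$edges$first_year[hit])
}

#' Decide whether a feature's association with the target is already known
#'
#' A feature is marked known (not novel) when either (i) it has at least one
#' linked entity and *every* linked entity is directly connected (1-hop) to
#' at least one target entity, or (ii) at least one *strongly* linked entity
#' (semantic similarity >= `theta_sim`) has a direct connection to a target
#' entity. Unlinked features are treated as novel by default: the screen
#' prioritizes precision in exclusion.
#'
#' @param feature_links Gated link data frame (from [similarity_gate()]),
#'   with columns `entity_id` and `strong` (a `sim` column is used to
#'   recompute `strong` if absent).
#' @param target_entities Character vector of target entity ids (nonempty).
#' @param kg `knowledge_graph` object.
#' @param theta_sim Strong-link threshold used if `strong` must be derived.
#' @return List (class `novelty_verdict`): `known`, `reason` (one of
#'   `all-linked-1hop`, `strong-link-1hop`, `not-known`, `unlinked`), and
#'   `witnesses` (entity ids adjacent to the target).
#' @export
is_known <- function(feature_links, target_entities, kg, theta_sim = 0.4) {
  if (length(target_entities) == 0) stop("is_known: no target entities")
  verdict <- function(known, reason, witnesses = character())
    structure(list(known = known, reason = reason, witnesses = witnesses),
              class = "novelty_verdict")
  if (is.null(feature_links) || nrow(feature_links) == 0)
    return(verdict(FALSE, "unlinked"))
  strong <- feature_links$strong
  if (is.null(strong)) {
    if (is.null(feature_links$sim)) stop("is_known: links lack strong/sim")
    strong <- feature_links$sim >= theta_sim
  }
  adj <- vapply(feature_links$entity_id, function(e)
    any(kg_adjacent(kg, rep(e, length(target_entities)), target_entities)),
    logical(1), USE.NAMES = FALSE)
  if (all(adj))
    return(verdict(TRUE, "all-linked-1hop", feature_links$entity_id[adj]))
  if (any(strong & adj))
    return(verdict(TRUE, "strong-link-1hop",
                   feature_links$entity_id[strong & adj]))
  verdict(FALSE, "not-known", feature_links$entity_id[adj])
}

#' Split a knowledge graph at a temporal cutoff
#'
#' @param kg `knowledge_graph` object; every edge must carry `first_year`.
#' @param cutoff_year Calendar year; edges first reported in or before it go
#'   to the historical graph.
#' @return List `kg_pre` (edges with `first_year <= cutoff_year`) and
#'   `kg_post_only` (the complement); their union is the input graph.
#' @export
temporal_split <- function(kg, cutoff_year) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (any(!is.finite(kg$edges$first_year)))
    stop("temporal_split: edges missing first_year: ",
         paste(which(!is.finite(kg$edges$first_year)), collapse = ", "))
  pre <- kg; post <- kg
  keep <- kg$edges$first_year <= cutoff_year
  pre$edges <- kg$edges[keep, , drop = FALSE]
  post$edges <- kg$edges[!keep, , drop = FALSE]
  rownames(pre$edges) <- rownames(post$edges) <- NULL
  list(kg_pre = pre, kg_post_only = post)
}

#' Temporal validation of utility-filtered features
#'
#' Runs the time-split reality check: among utility-filtered features, count
#' (i) those with at least one KG-linked entity, (ii) those directly
#' connected (1-hop) to the target in the full graph, and (iii) those whose
#' earliest feature-target edge was first reported *after* the cutoff year.
#' A post-cutoff first report means the association entered the knowledge
#' base only after the screening data's era, i.e. the screen surfaced it
#' ahead of its recognition. The proportion (iii)/(ii) is reported with a
#' 95% Wilson score interval.
#'
#' @param utility_features Character vector of feature ids that passed the
#'   utility filter.
#' @param feature_links Named list: feature id -> gated link data frame.
#' @param target_entities Target entity ids.
#' @param kg Full (all-years) `knowledge_graph`.
#' @param cutoff_year Temporal cutoff.
#' @return List: `n_linked`, `n_onehop`, `n_post`, `prop` (share of 1-hop
#'   features that are post-cutoff), `ci` (Wilson bounds), `percent` and
#'   `percent_ci` (rounded to integer percent), `per_feature` data frame.
#' @export
temporal_validation <- function(utility_features, feature_links,
                                target_entities, kg, cutoff_year) {
  stopifnot(inherits(kg, "knowledge_graph"))
  rows <- lapply(utility_features, function(f) {
    links <- feature_links[[f]]
    linked <- !is.null(links) && nrow(links) > 0
    yr <- if (linked)
      min(vapply(links$entity_id, kg_first_year, numeric(1),
                 target_entities = target_entities, kg = kg)) else Inf
    data.frame(feature = f, linked = linked, onehop = is.finite(yr),
               first_year = ifelse(is.finite(yr), yr, NA_real_),
               post_cutoff = is.finite(yr) && yr > cutoff_year,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  n_linked <- sum(per$linked)
  n_onehop <- sum(per$onehop)
  n_post <- sum(per$post_cutoff)
  if (n_onehop > 0) {
    ci <- wilson_ci(n_post, n_onehop)
    prop <- n_post / n_onehop
  } else {
    ci <- c(lower = 0, upper = 1)
    prop <- 0
  }
  list(n_linked = n_linked, n_onehop = n_onehop, n_post = n_post,
       prop = prop, ci = ci,
       percent = round(100 * prop), percent_ci = round(100 * ci),
       per_feature = per)
}
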