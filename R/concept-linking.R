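# Deterministic offline concept linker + embedder.
#
# The linker scores lexicon entries by token-overlap (Jaccard) between the
# normalized query text and the entity name; the embedder maps text to a
# fixed-dimension hashed character-trigram count vector. Both are exact,
# dependency-free and reproducible byte-for-byte, which is what the test
# suite and the synthetic pipeline need. Real biomedical linkers/embedders
# can be plugged in through the same provider interface.

norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  gsub("\\s+", " ", trimws(x))
}

tokenize <- function(x) {
  toks <- strsplit(norm_text(x), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

# Hashed character-trigram embedding; rolling polynomial hash mod `dim`.
hash_embed <- function(text, dim = 256L) {
  s <- paste0(" ", norm_text(text), " ")
  v <- numeric(dim)
  n <- nchar(s)
  if (n < 3) return(v)
  codes <- utf8ToInt(s)
  for (i in seq_len(n - 2)) {
    h <- 0
    for (j in i:(i + 2)) h <- (h * 31 + codes[j]) %% dim
    v[h + 1] <- v[h + 1] + 1
  }
  v
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine_sim: zero-norm embedding; similarity treated as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Deterministic offline entity linker and embedder over a lexicon
#'
#' Builds a concept-linking provider from an entity lexicon
#' (`entity_id`, `name`, `category`). `link(text)` returns candidate
#' entities scored by token-overlap between the query and the entity name
#' (an exact normalized match scores 1); `embed(text)` returns a hashed
#' character-trigram vector for cosine similarity. Deterministic for fixed
#' input, so every downstream gate is reproducible.
#'
#' @param lexicon Data frame with columns `entity_id`, `name`, `category`.
#' @param dim Embedding dimension, default 256.
#' @return Provider: list with `link(text)`, `embed(text)`, and the lexicon.
#' @export
lexicon_provider <- function(lexicon, dim = 256L) {
  stopifnot(is.data.frame(lexicon),
            all(c("entity_id", "name", "category") %in% names(lexicon)))
  if (anyDuplicated(lexicon$entity_id))
    stop("lexicon_provider: duplicate entity ids")
  name_tokens <- lapply(lexicon$name, tokenize)
  list(
    link = function(text) {
      q <- tokenize(text)
      if (length(q) == 0) return(data.frame(entity_id = character(),
                                            surface = character(),
                                            confidence = numeric()))
      score <- vapply(name_tokens, function(nt) {
        if (length(nt) == 0) return(0)
        length(intersect(q, nt)) / length(union(q, nt))
      }, numeric(1))
      keep <- which(score > 0)
      out <- data.frame(entity_id = lexicon$entity_id[keep],
                        surface = lexicon$name[keep],
                        confidence = score[keep],
                        stringsAsFactors = FALSE)
      out[order(-out$confidence, out$entity_id), , drop = FALSE]
    },
    embed = function(text) hash_embed(text, dim = dim),
    lexicon = lexicon
  )
}

#' Read an entity lexicon from CSV
#'
#' @param path CSV file with header `entity_id,name,category`.
#' @return Data frame lexicon.
#' @export
read_lexicon <- function(path) {
  lex <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("entity_id", "name", "category") %in% names(lex)))
  lex
}

empty_links <- function(feature_text = "") {
  out <- data.frame(entity_id = character(), surface = character(),
                    confidence = numeric(), name = character(),
                    category = character(), stringsAsFactors = FALSE)
  attr(out, "feature_text") <- feature_text
  out
}

#' Link a feature's text to knowledge-graph entities
#'
#' Queries the provider and keeps at most `max_entities` candidate entities
#' with linker confidence at or above `min_link_score`, ordered by
#' confidence descending (ties broken by entity id, so truncation is
#' stable). An empty result is valid: the feature proceeds as "unlinked".
#'
#' @param text Feature name/description text (nonempty).
#' @param provider A linking provider, e.g. [lexicon_provider()].
#' @param max_entities Maximum entities kept per feature, default 3.
#' @param min_link_score Minimum linker confidence, default 0.88.
#' @return Data frame of links (`entity_id`, `surface`, `confidence`,
#'   `name`, `category`) with the query text stored in the
#'   `feature_text` attribute.
#' @export
link_feature <- function(text, provider, max_entities = 3L, min_link_score = 0.88) {
  if (!nzchar(trimws(text))) stop("link_feature: empty feature text")
  cand <- tryCatch(provider$link(text),
                   error = function(e) stop("link_feature: provider failed for '",
                                            text, "': ", conditionMessage(e)))
  cand <- cand[cand$confidence >= min_link_score, , drop = FALSE]
  cand <- cand[order(-cand$confidence, cand$entity_id), , drop = FALSE]
  cand <- head(cand, max_entities)
  lex <- provider$lexicon
  idx <- match(cand$entity_id, lex$entity_id)
  cand$name <- lex$name[idx]
  cand$category <- lex$category[idx]
  cand$name[is.na(cand$name)] <- cand$surface[is.na(cand$name)]
  cand$category[is.na(cand$category)] <- ""
  rownames(cand) <- NULL
  attr(cand, "feature_text") <- text
  cand
}

#' Remove links whose entity category matches an exclusion pattern
#'
#' High-level or uninformative semantic categories (e.g. "Qualification",
#' "Unit", or the target's own "Disease" class) are excluded by
#' case-insensitive regex over the entity category and canonical name.
#'
#' @param links Link data frame from [link_feature()].
#' @param patterns Character vector of regexes (validated at config load).
#' @return Filtered link data frame (query-text attribute preserved).
#' @export
exclude_categories <- function(links, patterns) {
  ft <- attr(links, "feature_text")
  if (length(patterns) == 0 || nrow(links) == 0) {
    attr(links, "feature_text") <- ft
    return(links)
  }
  for (p in patterns) {
    ok <- tryCatch({grepl(p, ""); TRUE}, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("exclude_categories: invalid regex: ", p)
  }
  hit <- rep(FALSE, nrow(links))
  for (p in patterns)
    hit <- hit | grepl(p, links$category, ignore.case = TRUE) |
      grepl(p, links$name, ignore.case = TRUE)
  out <- links[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_text") <- ft
  out
}

#' Gate links by semantic similarity to the feature text
#'
#' Computes cosine similarity between the feature text and each entity's
#' canonical name using the provider's embedder; drops links with very low
#' similarity (`sim < low_sim`) and flags the survivors as strongly linked
#' when `sim >= theta_sim`. A strongly linked entity (e.g. "alcohol" for the
#' feature "alcohol intake") can later mark the feature as known on its own.
#'
#' @param links Link data frame from [link_feature()].
#' @param provider Provider with an `embed(text)` function.
#' @param feature_text Feature text; defaults to the attribute stored on
#'   `links`.
#' @param low_sim Removal threshold, default 0.1.
#' @param theta_sim Strong-link threshold, default 0.4 (boundary counts as
#'   strong).
#' @return Link data frame with added `sim` and `strong` columns.
#' @export
similarity_gate <- function(links, provider,
                            feature_text = attr(links, "feature_text"),
                            low_sim = 0.1, theta_sim = 0.4) {
  ft <- feature_text
  if (nrow(links) == 0) {
    out <- links
    out$sim <- numeric(0)
    out$strong <- logical(0)
    attr(out, "feature_text") <- ft
    return(out)
  }
  if (is.null(ft)) stop("similarity_gate: feature text unavailable")
  qv <- provider$embed(ft)
  if (is.null(links$sim)) {
    links$sim <- vapply(links$name, function(nm)
      cosine_sim(qv, provider$embed(nm)), numeric(1), USE.NAMES = FALSE)
  }
  out <- links[links$sim >= low_sim, , drop = FALSE]
  out$strong <- out$sim >= theta_sim
  rownames(out) <- NULL
  attr(out, "feature_text") <- ft
  out
}
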