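# Shared fixtures, built in code.

# Small planted-feature panel: one novel, one KG-known, one literature-known.
small_planted <- function() {
  data.frame(feature = c("serum_urate", "alcohol_intake", "shoe_size_marker"),
             effect = c(1.2, 1.0, 1.0),
             kg_known = c(FALSE, TRUE, FALSE),
             lit_known = c(FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

small_world <- function(seed = 11, n = 2000, n_null = 30, missing_rate = 0.05) {
  spec <- synthetic_spec(n, n_null, 0.1, small_planted(),
                         missing_rate = missing_rate, seed = seed)
  generate_world(spec)
}

run_small_screen <- function(seed = 11, ...) {
  w <- small_world(seed = seed, ...)
  scr <- feature_screen(w$cohort, w$target_name, w$target_entities, w$kg,
                        w$link_provider, w$lit_provider, w$llm_provider,
                        w$corpus, config = screen_config(seed = seed))
  list(world = w, screen = scr)
}

# A 6-node toy graph for exhaustive checks of the known-association rule.
# Entities e1..e4 are feature-side; t1, t2 are targets.
toy_rule_kg <- function(adjacent = c("e1", "e2")) {
  edges <- data.frame(
    subject_cui = c(adjacent, "e3"),
    object_cui = c(rep("t1", length(adjacent)), "e4"),
    n_citations = 3, first_year = 2000, stringsAsFactors = FALSE)
  kg_from_edges(edges)
}

# Brute-force evaluation of the known-association rule, written directly
# from its definition, independent of is_known()'s implementation.
brute_force_known <- function(entities, strong, adjacent_set) {
  if (length(entities) == 0) return(FALSE)
  adj <- entities %in% adjacent_set
  all(adj) || any(strong & adj)
}

# Stub linking provider with fully controlled confidences and embeddings.
stub_provider <- function(link_table, embeddings = NULL) {
  list(
    link = function(text) link_table,
    embed = function(text) {
      if (is.null(embeddings)) stop("no embeddings stubbed")
      embeddings[[text]]
    },
    lexicon = data.frame(entity_id = link_table$entity_id,
                         name = link_table$surface,
                         category = link_table$category %||%
                           rep("Finding", nrow(link_table)),
                         stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a validation scenario with exact counts: n_linked features each
# linked to their own entity; n_onehop of them have an edge to the target,
# n_post of those first reported after the cutoff.
counts_scenario <- function(n_linked, n_onehop, n_post, cutoff = 2011) {
  feats <- sprintf("f%04d", seq_len(n_linked))
  ents <- sprintf("E%04d", seq_len(n_linked))
  yr <- c(rep(cutoff + 2, n_post), rep(cutoff - 5, n_onehop - n_post))
  edges <- data.frame(subject_cui = ents[seq_len(n_onehop)],
                      object_cui = "TGT", n_citations = 3, first_year = yr)
  # background edge so the graph is never empty even with n_onehop = 0
  edges <- rbind(edges, data.frame(subject_cui = "Ebg1", object_cui = "Ebg2",
                                   n_citations = 3, first_year = 2000))
  kg <- kg_from_edges(edges)
  links <- setNames(lapply(ents, function(e)
    data.frame(entity_id = e, sim = 1, strong = TRUE)), feats)
  temporal_validation(feats, links, "TGT", kg, cutoff)
}
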