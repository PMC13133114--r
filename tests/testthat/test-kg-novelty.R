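write_triples <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

test_that("graph loading enforces evidence, symmetry and merging rules", {
  df <- data.frame(
    subject_cui = c("a", "b", "a", "c", "d", "e", "f", "g", "h", "i"),
    predicate = c("P1", "P2", "P3", "P1", "P1", "P1", "P1", "P1", "P1", "P1"),
    object_cui = c("b", "a", "c", "d", "e", "f", "g", "h", "i", "j"),
    n_citations = c(3, 5, 1, 2, 2, 1, 1, 1, 4, 2),
    first_year = c(2001, 1999, 2005, 2010, 2011, 2000, 2000, 2000, 2012, 2013))
  kg <- load_kg(write_triples(df))
  # (a,b) and (b,a) merge into one undirected edge: max evidence, min year
  ab <- kg$edges[kg$edges$a == "a" & kg$edges$b == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$evidence_count, 5)
  expect_equal(ab$first_year, 1999)
  # single-citation edges are gone
  expect_false(kg_adjacent(kg, "a", "c"))
  # 10 raw rows, 4 below the evidence threshold, one duplicate pair -> 5 edges
  expect_equal(nrow(kg$edges), 5)
})

test_that("malformed triple rows are rejected with their line number", {
  df <- data.frame(subject_cui = c("a", ""), predicate = "P",
                   object_cui = c("b", "c"), n_citations = c(2, 2),
                   first_year = c(2000, 2000))
  expect_error(load_kg(write_triples(df)), "line")
  df2 <- data.frame(subject_cui = "a", predicate = "P", object_cui = "b",
                    n_citations = "not a number", first_year = 2000)
  expect_error(load_kg(write_triples(df2)), "line")
})

test_that("entities missing from the lexicon are auto-registered", {
  df <- data.frame(subject_cui = "a", predicate = "P", object_cui = "b",
                   n_citations = 2, first_year = 2000)
  lex <- data.frame(entity_id = "a", name = "concept a", category = "Finding")
  expect_warning(kg <- load_kg(write_triples(df), lexicon = lex),
                 "auto-registering")
  expect_true("b" %in% kg$lexicon$entity_id)
  expect_equal(kg$lexicon$category[kg$lexicon$entity_id == "b"], "")
})

test_that("the known-association rule fires on its two clauses only", {
  kg <- toy_rule_kg(adjacent = c("e1", "e2"))
  links <- function(ids, strong) {
    if (length(ids) == 0) return(data.frame(entity_id = character(),
                                            strong = logical()))
    data.frame(entity_id = ids, strong = strong, stringsAsFactors = FALSE)
  }
  # all linked entities adjacent to the target
  v <- is_known(links(c("e1", "e2"), c(FALSE, FALSE)), "t1", kg)
  expect_true(v$known); expect_equal(v$reason, "all-linked-1hop")
  # one strong adjacent among non-adjacent others
  v <- is_known(links(c("e1", "e3", "e4"), c(TRUE, FALSE, FALSE)), "t1", kg)
  expect_true(v$known); expect_equal(v$reason, "strong-link-1hop")
  # weak links, only one adjacent: neither clause fires
  v <- is_known(links(c("e1", "e3"), c(FALSE, FALSE)), "t1", kg)
  expect_false(v$known); expect_equal(v$reason, "not-known")
  # unlinked features are novel by default
  v <- is_known(links(character(), logical()), "t1", kg)
  expect_false(v$known); expect_equal(v$reason, "unlinked")
  expect_error(is_known(links("e1", TRUE), character(), kg), "target")
})

test_that("the rule agrees with brute force on every link set of size <= 3", {
  kg <- toy_rule_kg(adjacent = c("e1", "e2"))
  adjacent_set <- c("e1", "e2")
  ents <- c("e1", "e2", "e3", "e4")
  cases <- 0
  for (k in 0:3) {
    combos <- if (k == 0) list(character()) else
      combn(ents, k, simplify = FALSE)
    for (ids in combos) {
      strong_grid <- if (k == 0) list(logical()) else
        lapply(seq_len(2^k) - 1,
               function(m) as.logical(bitwAnd(bitwShiftR(m, seq_len(k) - 1), 1)))
      for (strong in strong_grid) {
        links <- data.frame(entity_id = ids, strong = strong,
                            stringsAsFactors = FALSE)
        got <- is_known(links, "t1", kg)$known
        want <- brute_force_known(ids, strong, adjacent_set)
        expect_identical(got, want)
        cases <- cases + 1
      }
    }
  }
  expect_gte(cases, 30)
})

test_that("adding an edge never flips a verdict from known to novel", {
  set.seed(6)
  ents <- sprintf("e%d", 1:5)
  for (rep in 1:25) {
    n_edge <- sample(0:4, 1)
    adj <- sample(ents, n_edge)
    kg_small <- toy_rule_kg(adjacent = adj)
    extra <- setdiff(ents, adj)
    kg_big <- toy_rule_kg(adjacent = c(adj, extra[seq_len(min(1, length(extra)))]))
    k <- sample(1:3, 1)
    links <- data.frame(entity_id = sample(ents, k),
                        strong = sample(c(TRUE, FALSE), k, replace = TRUE),
                        stringsAsFactors = FALSE)
    if (is_known(links, "t1", kg_small)$known)
      expect_true(is_known(links, "t1", kg_big)$known)
  }
})

test_that("temporal splits partition the graph at the cutoff", {
  df <- data.frame(subject_cui = c("a", "b", "c"), predicate = "P",
                   object_cui = c("b", "c", "d"), n_citations = 3,
                   first_year = c(2005, 2011, 2012))
  kg <- load_kg(write_triples(df))
  sp <- temporal_split(kg, 2011)
  expect_equal(nrow(sp$kg_pre$edges), 2)      # 2011 counts as pre (<=)
  expect_equal(nrow(sp$kg_post_only$edges), 1)
  expect_equal(sp$kg_post_only$edges$first_year, 2012)
  expect_equal(nrow(sp$kg_pre$edges) + nrow(sp$kg_post_only$edges),
               nrow(kg$edges))
  all_pre <- load_kg(write_triples(transform(df, first_year = 2005)))
  expect_equal(nrow(temporal_split(all_pre, 2011)$kg_post_only$edges), 0)
})


test_that("temporal validation reproduces the published worked examples", {
  tv <- counts_scenario(920, 274, 58)
  expect_equal(tv$n_linked, 920)
  expect_equal(tv$n_onehop, 274)
  expect_equal(tv$n_post, 58)
  expect_equal(tv$percent, 21)
  expect_equal(unname(tv$percent_ci), c(17, 26))

  tv0 <- counts_scenario(40, 10, 0)
  expect_equal(tv0$percent, 0)
  expect_equal(unname(tv0$percent_ci), c(0, 28))
  # denominators are nested
  expect_lte(tv$n_post, tv$n_onehop)
  expect_lte(tv$n_onehop, tv$n_linked)
})
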