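test_that("signatures canonicalize component order and discriminate on content", {
  ents <- entity_tbl(P = "complex", Q = "complex", R = "complex",
                     S = "complex", A = "protein", B = "protein")
  # P and Q list {2A, 1B} in opposite orders; R differs in stoichiometry,
  # S in location
  comps <- dplyr::bind_rows(
    edge_tbl(c("P", "P"), c("A", "B"), c(2, 1)),
    edge_tbl(c("Q", "Q"), c("B", "A"), c(1, 2)),
    edge_tbl(c("R", "R"), c("A", "B"), c(1, 1)),
    edge_tbl(c("S", "S"), c("A", "B"), c(2, 1))
  )
  locs <- tibble::tibble(complex_iri = ex(c("P", "Q", "R", "S")),
                         location_iri = ex(c("L1", "L1", "L1", "L2")))
  g <- bp_graph(ents, comps, locs)
  sig <- bp_signatures(g)
  s <- function(x) sig$signature[sig$iri == ex(x)]
  expect_identical(s("P"), s("Q"))
  expect_false(identical(s("P"), s("R")))  # {2A} vs {1A}
  expect_false(identical(s("P"), s("S")))  # location discriminates
  # ignoring location merges P, Q, S
  pairs_noloc <- bp_redundant_pairs(g, ignore_location = TRUE)
  expect_equal(nrow(pairs_noloc), 3L)
  expect_equal(nrow(bp_redundant_pairs(g)), 1L)
})

test_that("absent location matches only absent location", {
  ents <- entity_tbl(P = "complex", Q = "complex", R = "complex",
                     A = "protein")
  comps <- edge_tbl(c("P", "Q", "R"), c("A", "A", "A"), c(1, 1, 1))
  locs <- tibble::tibble(complex_iri = ex("P"), location_iri = ex("L1"))
  g <- bp_graph(ents, comps, locs)
  pairs <- bp_redundant_pairs(g)
  expect_equal(nrow(pairs), 1L)  # only the two location-less ones
  expect_setequal(c(pairs$iri_a, pairs$iri_b), ex(c("Q", "R")))
})

test_that("black-box complexes are never reported as redundant", {
  ents <- entity_tbl(B1 = "complex", B2 = "complex")
  g <- bp_graph(ents)
  expect_equal(nrow(bp_redundant_pairs(g)), 0L)
})

test_that("a planted group of size 4 yields 6 pairs, matching all-pairs brute force", {
  g <- graph_planted_groups(4)
  pairs <- bp_redundant_pairs(g)
  expect_equal(nrow(pairs), 6L)
  # brute-force oracle: compare every unordered pair of signatures directly
  sig <- bp_signatures(g)
  brute <- 0L
  for (i in seq_len(nrow(sig) - 1)) {
    for (j in seq(i + 1, nrow(sig))) {
      if (identical(sig$signature[[i]], sig$signature[[j]])) brute <- brute + 1L
    }
  }
  expect_equal(nrow(pairs), brute)
})

test_that("groups are the maximal cliques with the k(k-1)/2 arithmetic", {
  g <- graph_planted_groups(c(2, 2, 6))
  red <- bp_redundancy(g)
  expect_equal(red$n_groups, 3L)
  expect_setequal(red$groups$size, c(2L, 2L, 6L))
  expect_setequal(red$groups$n_pairs, c(1L, 1L, 15L))
  expect_setequal(red$groups$excess, c(1L, 1L, 5L))
  expect_equal(red$n_pairs, 1L + 1L + 15L)
  expect_equal(red$n_excess, red$n_distinct - red$n_groups)

  # independent maximal-clique enumeration (Bron-Kerbosch) on the pair graph
  ig <- igraph::graph_from_data_frame(red$pairs[c("iri_a", "iri_b")],
                                      directed = FALSE)
  cliques <- igraph::max_cliques(ig)
  expect_equal(length(cliques), red$n_groups)
  oracle_members <- lapply(cliques, function(cl) sort(names(cl)))
  got_members <- red$groups$members
  expect_setequal(vapply(oracle_members, paste, character(1), collapse = "|"),
                  vapply(got_members, paste, character(1), collapse = "|"))
})

test_that("a non-transitive pair set raises an internal-consistency error", {
  fake <- tibble::tibble(iri_a = c("A", "B"), iri_b = c("B", "C"))
  expect_error(bp_group_pairs(fake), "internal-consistency")
})

test_that("three nestings of one composition become a 3-clique after fixing", {
  g <- graph_three_nestings()
  before <- bp_redundant_pairs(g)
  fixed <- bp_fix_all(g)$graph
  after <- bp_redundant_pairs(fixed)
  expect_equal(nrow(after), 3L)
  red <- bp_redundancy(fixed)
  top <- red$groups[vapply(red$groups$members,
                           function(m) all(ex(c("X1", "X2", "X3")) %in% m),
                           logical(1)), ]
  expect_equal(top$size, 3L)
  expect_equal(top$excess, 2L)
  # detection is monotone under fixing
  key <- function(p) paste(p$iri_a, p$iri_b)
  expect_true(all(key(before) %in% key(after)))
})

test_that("redundancy accounting identities hold on simulated data", {
  for (seed in 1:5) {
    g <- bp_simulate(fixture_config(seed = seed, n_redundant_groups = 2,
                                    n_complexes = 20))$graph
    red <- bp_redundancy(bp_fix_all(g)$graph)
    expect_equal(red$n_pairs,
                 sum(red$groups$size * (red$groups$size - 1) / 2))
    expect_equal(red$n_distinct, sum(red$groups$size))
    expect_equal(red$n_excess, red$n_distinct - red$n_groups)
  }
})

test_that("detected groups equal the generator's oracle-derived truth", {
  for (seed in 1:3) {
    sim <- bp_simulate(fixture_config(seed = seed, n_redundant_groups = 2,
                                      n_complexes = 20))
    red <- bp_redundancy(bp_fix_all(sim$graph)$graph)
    got <- sort(vapply(red$groups$members, paste, character(1),
                       collapse = "|"))
    want <- sort(vapply(sim$truth$groups$members, paste, character(1),
                        collapse = "|"))
    expect_equal(got, want)
  }
})

test_that("same-composition annotation adds k(k-1) directed statements per group", {
  g <- graph_planted_groups(c(2, 3))
  red <- bp_redundancy(g)
  annotated <- bp_annotate_same_composition(g, red)
  pred <- "http://example.org/complexfix-annotations#hasSameCompositionAs"
  added <- annotated$residual[annotated$residual$predicate == pred, ]
  expect_equal(nrow(added), 2L * 1L + 3L * 2L)
  # symmetric: both orientations present
  expect_setequal(paste(added$subject, added$object),
                  paste(added$object, added$subject))
  # original statements untouched
  expect_identical(
    as.data.frame(annotated$residual[annotated$residual$predicate != pred, ]),
    as.data.frame(g$residual))
  # no annotations for an empty group set
  g2 <- graph_xyz()
  expect_true(bp_graph_equal(
    bp_annotate_same_composition(g2, bp_redundancy(g2)), g2))
})
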