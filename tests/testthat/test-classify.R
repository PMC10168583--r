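test_that("composition graph exposes chains and diamonds correctly", {
  g <- graph_xyz()  # X -> {Y, Z}, Y -> Z: a diamond onto Z
  edges <- bp_composition_edges(g)
  expect_equal(nrow(edges), 3L)
  expect_equal(length(unique(c(edges$from, edges$to))), 3L)
  # Z is a component of several parts of the recursive complex
  expect_equal(sum(edges$to == ex("Z")), 2L)
})

test_that("self-containing complexes are reported as cycles, others still classified", {
  ents <- entity_tbl(X = "complex", Y = "complex", A = "protein")
  comps <- edge_tbl(c("X", "Y"), c("X", "A"), c(1, 1))
  g <- bp_graph(ents, comps)
  cyc <- bp_cycles(g)
  expect_equal(cyc$on_cycle, ex("X"))
  cls <- bp_classify(g)
  expect_true(cls$on_cycle[cls$iri == ex("X")])
  expect_true(is.na(cls$category[cls$iri == ex("X")]))
  expect_equal(cls$category[cls$iri == ex("Y")], "VALID_NON_RECURSIVE")
  expect_error(bp_composition_depth(g, ex("X")), "cycle")
})

test_that("ancestors of a cycle are also excluded from classification", {
  ents <- entity_tbl(Top = "complex", X = "complex", Y = "complex",
                     A = "protein")
  comps <- edge_tbl(c("Top", "X", "Y"), c("X", "Y", "X"), c(1, 1, 1))
  g <- bp_graph(ents, comps)
  cyc <- bp_cycles(g)
  expect_setequal(cyc$on_cycle, ex(c("X", "Y")))
  expect_setequal(cyc$affected, ex(c("Top", "X", "Y")))
})

test_that("each complex gets exactly one category matching the one-hop rule", {
  for (seed in 1:5) {
    g <- bp_simulate(fixture_config(seed = seed))$graph
    cls <- bp_classify(g)
    expect_false(any(is.na(cls$category)))
    # independent one-hop oracle: invalid iff some complex child has children
    edges <- bp_composition_edges(g)
    open_cx <- unique(edges$from)
    oracle <- vapply(cls$iri, function(cx) {
      kids <- edges$to[edges$from == cx]
      if (!length(kids)) return("BLACK_BOX")
      if (any(kids %in% open_cx)) "INVALID_RECURSIVE" else "VALID_NON_RECURSIVE"
    }, character(1))
    expect_equal(cls$category, unname(oracle[cls$iri]))
  }
})

test_that("depth equals the longest root-to-leaf path and coheres with category", {
  expect_equal(bp_composition_depth(graph_chain(10), ex("C10")), 10L)
  # X = {Y, Z} with Y = {A}: longest path has length 2
  ents <- entity_tbl(X = "complex", Y = "complex", Z = "protein",
                     A = "protein")
  comps <- edge_tbl(c("X", "X", "Y"), c("Y", "Z", "A"), c(1, 1, 1))
  expect_equal(bp_composition_depth(bp_graph(ents, comps), ex("X")), 2L)

  for (seed in 1:5) {
    cls <- bp_classify(bp_simulate(fixture_config(seed = seed))$graph)
    expect_equal(cls$category == "BLACK_BOX", cls$depth == 0L)
    expect_equal(cls$category == "INVALID_RECURSIVE", cls$depth >= 2L)
  }
})

test_that("census counts partition the complex set and match planted truth", {
  g0 <- bp_graph(entity_tbl(A = "protein"))
  expect_equal(sum(bp_census(g0)$n), 0L)

  for (seed in 1:5) {
    sim <- bp_simulate(fixture_config(seed = seed))
    census <- bp_census(sim$graph)
    expect_equal(sum(census$n), nrow(sim$graph$complexes))
    truth_counts <- table(sim$truth$complexes$category)
    for (cat in names(truth_counts)) {
      expect_equal(census$n[census$category == cat],
                   as.integer(truth_counts[[cat]]))
    }
  }
})

test_that("interaction census counts each interaction once", {
  ents <- entity_tbl(X = "complex", Y = "complex", S = "complex",
                     A = "protein", B = "protein")
  comps <- edge_tbl(c("X", "S", "Y", "Y"), c("S", "A", "A", "B"),
                    c(1, 1, 1, 1))
  ints <- tibble::tibble(
    interaction_iri = ex(c("I1", "I1", "I2")),
    participant_iri = ex(c("X", "A", "Y")),
    property = c("left", "right", "left")
  )
  g <- bp_graph(ents, comps, interactions = ints)
  invalid <- bp_classify(g) |>
    dplyr::filter(category == "INVALID_RECURSIVE") |>
    dplyr::pull(iri)
  expect_equal(invalid, ex("X"))
  hit <- bp_interaction_census(g, invalid)
  expect_equal(hit$interaction_iri, ex("I1"))
  expect_equal(attr(hit, "n_total"), 2L)
  expect_equal(nrow(bp_interaction_census(g, character(0))), 0L)

  # an interaction with two invalid participants contributes 1, not 2
  ints2 <- tibble::tibble(
    interaction_iri = ex(c("I1", "I1")),
    participant_iri = ex(c("X", "X2")),
    property = c("left", "right")
  )
  ents2 <- dplyr::bind_rows(ents, entity_tbl(X2 = "complex"))
  comps2 <- dplyr::bind_rows(comps, edge_tbl("X2", "S", 1))
  g2 <- bp_graph(ents2, comps2, interactions = ints2)
  expect_equal(nrow(bp_interaction_census(g2, ex(c("X", "X2")))), 1L)
})
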