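test_that("global stoichiometry follows the path-product recursion", {
  # X holds alpha Y and beta Z directly, Y holds gamma Z: S_X(Z) = alpha*gamma + beta
  expect_equal(bp_global_stoichiometry(graph_xyz(2, 3, 1), ex("X"), ex("Z")), 7)
  expect_equal(bp_global_stoichiometry(graph_xyz(5, 4, 2), ex("X"), ex("Z")), 22)
  expect_equal(bp_global_stoichiometry(graph_xyz(1, 1, 1), ex("X"), ex("Z")), 2)
  # S_z(z) = 1 for any entity
  expect_equal(bp_global_stoichiometry(graph_xyz(), ex("Z"), ex("Z")), 1)
  expect_equal(bp_global_stoichiometry(graph_xyz(), ex("X"), ex("X")), 1)
  # unreachable leaf is a domain error
  expect_error(bp_global_stoichiometry(graph_xyz(), ex("Y"), ex("X")),
               "not reachable")
})

test_that("dynamic program equals brute-force expansion on random DAGs", {
  set.seed(20260919)
  for (k in 1:40) {
    g <- random_dag_graph(n_atoms = sample(2:5, 1),
                          n_complexes = sample(2:7, 1))
    for (root in unique(g$components$complex_iri)) {
      oracle <- bp_expand_brute_force(g, root)
      dp <- bp_global_stoichiometry(g, root)
      expect_equal(dp$leaf, oracle$leaf)
      expect_equal(dp$coefficient, oracle$count)
    }
  }
})

test_that("leaves are the childless reachable entities, black boxes included", {
  ents <- entity_tbl(X = "complex", Y = "complex", BB = "complex",
                     A = "protein", B = "protein", C = "small-molecule")
  comps <- edge_tbl(c("X", "X", "X", "Y", "Y"),
                    c("Y", "C", "BB", "A", "B"), rep(1, 5))
  g <- bp_graph(ents, comps)
  expect_setequal(bp_leaves(g, ex("X")), ex(c("A", "B", "C", "BB")))
  # a black-box root has no components, hence no leaves
  expect_equal(bp_leaves(g, ex("BB")), character(0))
})

test_that("fixing flattens to leaves with summed path coefficients", {
  g <- graph_xyz(2, 3, 1)
  fixed <- bp_fix_complex(g, ex("X"))
  comp <- fixed$components[fixed$components$complex_iri == ex("X"), ]
  # the diamond's two paths onto Z collapse into a single direct edge
  expect_equal(comp$component_iri, ex("Z"))
  expect_equal(comp$coefficient, 7)
  expect_true(all(comp$explicit))
  # Y itself was untouched (it is valid)
  expect_equal(fixed$components$coefficient[
    fixed$components$complex_iri == ex("Y")], 3)
})

test_that("fixing a valid complex is a warning no-op", {
  g <- graph_xyz()
  expect_warning(out <- bp_fix_complex(g, ex("Y")), "not an invalid")
  expect_true(bp_graph_equal(out, g))
})

test_that("fix_all leaves depth <= 1, no invalid complexes, and is idempotent", {
  for (seed in 1:5) {
    g <- bp_simulate(fixture_config(seed = seed))$graph
    fx <- bp_fix_all(g)
    cls <- bp_classify(fx$graph)
    expect_true(all(cls$depth <= 1L))
    expect_false(any(cls$category == "INVALID_RECURSIVE"))
    fx2 <- bp_fix_all(fx$graph)
    expect_equal(fx2$n_fixed, 0L)
    expect_true(bp_graph_equal(fx2$graph, fx$graph))
  }
})

test_that("a deeply nested chain collapses onto its single leaf", {
  g <- graph_chain(10, coefficients = rep(2, 10))
  fx <- bp_fix_all(g)
  top <- fx$graph$components[fx$graph$components$complex_iri == ex("C10"), ]
  expect_equal(top$component_iri, ex("leaf"))
  expect_equal(top$coefficient, 2^10)
  expect_equal(max(bp_classify(fx$graph)$depth), 1L)
})

test_that("flattened multisets equal exhaustive expansion on every fixture", {
  for (seed in 1:5) {
    sim <- bp_simulate(fixture_config(seed = seed))
    fx <- bp_fix_all(sim$graph)
    truth <- sim$truth$complexes
    for (k in seq_len(nrow(truth))) {
      flat <- truth$flat[[k]]
      if (nrow(flat) == 0) next
      got <- fx$graph$components[
        fx$graph$components$complex_iri == truth$iri[[k]], ]
      got <- dplyr::arrange(got, component_iri)
      expect_equal(got$component_iri, flat$leaf)
      expect_equal(got$coefficient, flat$count)
    }
  }
})

test_that("fixing touches only component statements of fixed complexes", {
  sim <- bp_simulate(fixture_config(seed = 3))
  fx <- bp_fix_all(sim$graph)
  # every non-composition statement is untouched (step iv)
  expect_identical(as.data.frame(fx$graph$residual),
                   as.data.frame(sim$graph$residual))
  # entities and locations unchanged
  expect_identical(fx$graph$entities, sim$graph$entities)
  expect_identical(fx$graph$complexes, sim$graph$complexes)
  # intermediate complexes survive as standalone entities
  cls_b <- bp_classify(sim$graph)
  expect_true(all(cls_b$iri %in% bp_classify(fx$graph)$iri))
})

test_that("coefficients derived from defaulted edges are flagged in the report", {
  ents <- entity_tbl(X = "complex", Y = "complex", A = "protein",
                     B = "protein")
  comps <- edge_tbl(c("X", "X", "Y", "Y"), c("Y", "A", "A", "B"),
                    c(2, 1, 1, 3), explicit = c(TRUE, TRUE, FALSE, TRUE))
  g <- bp_graph(ents, comps)
  fx <- bp_fix_all(g)
  rep_x <- tidy(fx) |> dplyr::filter(iri == ex("X"))
  comp_x <- rep_x$composition[[1]]
  expect_true(comp_x$any_defaulted[comp_x$leaf == ex("A")])
  expect_false(comp_x$any_defaulted[comp_x$leaf == ex("B")])
  expect_equal(rep_x$n_defaulted_coefficients, 1L)
})

test_that("fix_all reports cycle-affected complexes instead of fixing them", {
  ents <- entity_tbl(X = "complex", Y = "complex", A = "protein")
  comps <- edge_tbl(c("X", "X", "Y"), c("Y", "A", "X"), c(1, 1, 1))
  g <- bp_graph(ents, comps)
  expect_error(bp_fix_all(g), "cycle")
  fx <- bp_fix_all(g, on_cycle = "skip")
  expect_setequal(fx$skipped, ex(c("X", "Y")))
  expect_equal(fx$n_fixed, 0L)
})

test_that("fix report is internally consistent", {
  sim <- bp_simulate(fixture_config(seed = 9))
  fx <- bp_fix_all(sim$graph)
  rep <- tidy(fx)
  unchanged <- rep[rep$category_before != "INVALID_RECURSIVE", ]
  expect_equal(unchanged$n_components_before, unchanged$n_components_after)
  fixed <- rep[rep$category_before == "INVALID_RECURSIVE", ]
  expect_true(all(fixed$n_components_after >= 1L))
  g <- glance(fx)
  expect_gte(g$mean_components_after, g$mean_components_before)
  expect_lte(g$max_depth_after, 1L)
})
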