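test_that("a minimal file with one componentless complex loads as a black box", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '  <bp:Complex rdf:about="http://example.org/test#BB"/>',
    '</rdf:RDF>'
  ), f)
  g <- read_biopax(f)
  expect_equal(nrow(g$complexes), 1L)
  expect_equal(nrow(g$components), 0L)
  expect_equal(bp_classify(g)$category, "BLACK_BOX")
})

test_that("coefficients written by the generator are read back exactly", {
  g <- graph_xyz(alpha = 2, gamma = 3, beta = 1)
  for (fmt in c("rdfxml", "turtle")) {
    f <- withr::local_tempfile(fileext = if (fmt == "turtle") ".ttl" else ".owl")
    write_biopax(g, f, format = fmt)
    g2 <- read_biopax(f)
    comp <- dplyr::arrange(g2$components, complex_iri, component_iri)
    expect_equal(comp$coefficient, c(2, 1, 3))
    expect_true(all(comp$explicit))
  }
})

test_that("component edges without stoichiometry default to 1 and are flagged", {
  # hand-written five-statement fixture: complex, component edge, two types,
  # one display name -- and no Stoichiometry node anywhere
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix bp: <http://www.biopax.org/release/biopax-level3.owl#> .",
    "@prefix ex: <http://example.org/test#> .",
    "ex:CX a bp:Complex ;",
    "  bp:component ex:P ;",
    '  bp:displayName "bare complex" .',
    "ex:P a bp:Protein ."
  ), f)
  g <- read_biopax(f)
  expect_equal(g$components$coefficient, 1)
  expect_false(g$components$explicit)
  # defaulting count equals the number of edges lacking stoichiometry
  expect_equal(sum(!g$components$explicit), 1L)
})

test_that("load-write-load round-trips preserve the graph in both dialects", {
  for (seed in 1:3) {
    g <- bp_simulate(fixture_config(seed = seed))$graph
    f_owl <- withr::local_tempfile(fileext = ".owl")
    f_ttl <- withr::local_tempfile(fileext = ".ttl")
    write_biopax(g, f_owl)
    write_biopax(g, f_ttl)
    g_owl <- read_biopax(f_owl)
    g_ttl <- read_biopax(f_ttl)
    expect_true(bp_graph_equal(g, g_owl))
    expect_true(bp_graph_equal(g, g_ttl))
    # write what was loaded: identical statement sets again
    f2 <- withr::local_tempfile(fileext = ".owl")
    write_biopax(g_ttl, f2)
    expect_true(bp_graph_equal(read_biopax(f2), g_owl))
  }
})

test_that("rdflib agrees the two serializations are the same RDF graph", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  g <- bp_simulate(fixture_config(seed = 5))$graph
  f_owl <- withr::local_tempfile(fileext = ".owl")
  f_ttl <- withr::local_tempfile(fileext = ".ttl")
  write_biopax(g, f_owl)
  write_biopax(g, f_ttl)
  script <- paste(
    "import sys, rdflib",
    "from rdflib.compare import isomorphic",
    "a = rdflib.Graph(); a.parse(sys.argv[1], format='xml')",
    "b = rdflib.Graph(); b.parse(sys.argv[2], format='turtle')",
    "sys.exit(0 if isomorphic(a, b) and len(a) > 0 else 1)",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, f_owl, f_ttl))
  skip_if(status == 127L, "python failed to start")
  expect_equal(status, 0L)
})

test_that("opaque statements survive untouched and annotations stay separate", {
  # an unknown predicate must round-trip bit-identically
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix bp: <http://www.biopax.org/release/biopax-level3.owl#> .",
    "@prefix ex: <http://example.org/test#> .",
    "ex:CX a bp:Complex ;",
    '  ex:curatorNote "checked 2022-06-13"@en ;',
    "  bp:component ex:P .",
    "ex:P a bp:Protein ."
  ), f)
  g <- read_biopax(f)
  note <- g$residual[g$residual$predicate == ex("curatorNote"), ]
  expect_equal(note$object, "checked 2022-06-13")
  expect_equal(note$lang, "en")
  f2 <- withr::local_tempfile(fileext = ".ttl")
  write_biopax(g, f2)
  g2 <- read_biopax(f2)
  expect_true(bp_graph_equal(g, g2))
})

test_that("non-Level-3 and malformed files are rejected with located errors", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:bp="http://www.biopax.org/release/biopax-level2.owl#">',
    '  <bp:complex rdf:about="http://example.org/test#BB"/>',
    '</rdf:RDF>'
  ), f)
  expect_error(read_biopax(f), "Level 3")

  f_bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix bp: <http://www.biopax.org/release/biopax-level3.owl#> .",
    "ex:CX a bp:Complex ."  # undeclared prefix
  ), f_bad)
  expect_error(read_biopax(f_bad), "prefix")

  f_junk <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix bp: <http://x#> .", "} not turtle {"), f_junk)
  expect_error(read_biopax(f_junk), "line")
})

test_that("component edges to undeclared entities raise a referential error", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix bp: <http://www.biopax.org/release/biopax-level3.owl#> .",
    "@prefix ex: <http://example.org/test#> .",
    "ex:CX a bp:Complex ; bp:component ex:ghost ."
  ), f)
  expect_error(read_biopax(f), "referential.*ghost")
})
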