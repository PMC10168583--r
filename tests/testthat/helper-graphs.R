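# in-code fixture builders shared across the suite

ex <- function(local) paste0("http://example.org/test#", local)

entity_tbl <- function(...) {
  kinds <- c(...)
  tibble::tibble(iri = ex(names(kinds)), kind = unname(kinds))
}

edge_tbl <- function(from, to, coefficient, explicit = TRUE) {
  tibble::tibble(complex_iri = ex(from), component_iri = ex(to),
                 coefficient = coefficient, explicit = explicit)
}

# X contains alpha*Y and beta*Z directly; Y contains gamma*Z
graph_xyz <- function(alpha = 2, gamma = 3, beta = 1) {
  bp_graph(
    entity_tbl(X = "complex", Y = "complex", Z = "protein"),
    edge_tbl(c("X", "X", "Y"), c("Y", "Z", "Z"), c(alpha, beta, gamma))
  )
}

# chain of n nested complexes C1..Cn ending in one atomic leaf
graph_chain <- function(n, coefficients = rep(1, n)) {
  cx <- paste0("C", seq_len(n))
  ents <- tibble::tibble(
    iri = ex(c(cx, "leaf")),
    kind = c(rep("complex", n), "protein")
  )
  # Cn -> Cn-1 -> ... -> C1 -> leaf
  from <- cx
  to <- c("leaf", cx[-n])
  bp_graph(ents, edge_tbl(from, to, coefficients))
}

# the three-way redundancy pattern: [A,(B,C)], [(A,C),B], [(A,B),C],
# all at one location, all coefficients 1
graph_three_nestings <- function() {
  ents <- entity_tbl(
    A = "protein", B = "protein", C = "protein",
    X1 = "complex", X2 = "complex", X3 = "complex",
    S_BC = "complex", S_AC = "complex", S_AB = "complex"
  )
  comps <- edge_tbl(
    c("X1", "X1", "S_BC", "S_BC",
      "X2", "X2", "S_AC", "S_AC",
      "X3", "X3", "S_AB", "S_AB"),
    c("A", "S_BC", "B", "C",
      "B", "S_AC", "A", "C",
      "C", "S_AB", "A", "B"),
    rep(1, 12)
  )
  locs <- tibble::tibble(complex_iri = ex(c("X1", "X2", "X3")),
                         location_iri = ex("LOC_cytosol"))
  bp_graph(ents, comps, locs)
}

# k flat complexes with identical composition and location (one group)
graph_planted_groups <- function(sizes) {
  ents <- list(entity_tbl(A = "protein", B = "protein", C = "protein"))
  comps <- list()
  locs <- list()
  for (g in seq_along(sizes)) {
    for (m in seq_len(sizes[[g]])) {
      cx <- sprintf("G%d_M%d", g, m)
      ents[[length(ents) + 1L]] <- entity_tbl(stats::setNames("complex", cx))
      # group-specific coefficient on A makes signatures differ across groups
      comps[[length(comps) + 1L]] <- edge_tbl(
        c(cx, cx), c("A", "B"), c(g, 1))
      locs[[length(locs) + 1L]] <- tibble::tibble(
        complex_iri = ex(cx), location_iri = ex("LOC1"))
    }
  }
  bp_graph(dplyr::bind_rows(ents), dplyr::bind_rows(comps),
           dplyr::bind_rows(locs))
}

# a small random composition DAG as a component table (cheap; used for
# property-style sweeps), with diamonds; returns a bp_graph
random_dag_graph <- function(n_atoms = 4, n_complexes = 6, max_children = 4,
                             coef_max = 5) {
  atoms <- sprintf("a%02d", seq_len(n_atoms))
  cx <- sprintf("c%02d", seq_len(n_complexes))
  ents <- tibble::tibble(iri = ex(c(atoms, cx)),
                         kind = c(rep("protein", n_atoms),
                                  rep("complex", n_complexes)))
  rows <- list()
  for (k in seq_len(n_complexes)) {
    n_kids <- sample(seq_len(max_children), 1)
    # at most two complex children per node keeps the number of
    # root-to-leaf paths tractable for the exhaustive oracle
    n_cx <- min(sample(0:2, 1), k - 1, n_kids)
    kids <- unique(c(
      if (n_cx > 0) sample(cx[seq_len(k - 1)], n_cx),
      sample(atoms, n_kids - n_cx, replace = TRUE)
    ))
    rows[[k]] <- edge_tbl(rep(cx[[k]], length(kids)), kids,
                          sample(coef_max, length(kids), replace = TRUE))
  }
  bp_graph(ents, dplyr::bind_rows(rows))
}
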