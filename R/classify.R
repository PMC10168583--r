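#' Composition graph of a BioPAX graph
#'
#' The directed complex-to-component multidigraph: one node per physical
#' entity reachable from any complex, one edge per direct component
#' relation, each carrying its stoichiometric coefficient and the
#' `explicit` flag. Non-complex nodes have out-degree zero by construction.
#'
#' @param graph A `biopax_graph`.
#' @return A tibble with columns `from` (complex), `to` (component),
#'   `coefficient`, `explicit`.
#' @export
bp_composition_edges <- function(graph) {
  stopifnot(inherits(graph, "biopax_graph"))
  graph$components |>
    dplyr::transmute(from = .data$complex_iri, to = .data$component_iri,
                     coefficient = .data$coefficient,
                     explicit = .data$explicit)
}

## adjacency list keyed by parent IRI; the workhorse representation for the
## recursive traversals
adjacency_list <- function(edges) {
  split(edges[c("to", "coefficient", "explicit")], edges$from)
}

#' Detect composition cycles
#'
#' A complex transitively containing itself violates the composition model
#' and makes depth and stoichiometry undefined for every complex on or
#' above the cycle. Detection uses strongly connected components.
#'
#' @param graph A `biopax_graph` or an edge tibble from
#'   [bp_composition_edges()].
#' @return A list with `on_cycle` (IRIs inside some cycle) and `affected`
#'   (those plus every ancestor that can reach a cycle).
#' @export
bp_cycles <- function(graph) {
  edges <- if (inherits(graph, "biopax_graph")) {
    bp_composition_edges(graph)
  } else {
    graph
  }
  if (nrow(edges) == 0) {
    return(list(on_cycle = character(0), affected = character(0)))
  }
  ig <- igraph::graph_from_data_frame(edges[c("from", "to")])
  scc <- igraph::components(ig, mode = "strong")
  sizes <- table(scc$membership)
  big <- names(sizes)[sizes > 1]
  on_cycle <- names(scc$membership)[scc$membership %in% as.integer(big)]
  self <- edges$from[edges$from == edges$to]
  on_cycle <- union(on_cycle, self)
  if (!length(on_cycle)) {
    return(list(on_cycle = character(0), affected = character(0)))
  }
  affected <- unique(unlist(lapply(on_cycle, function(v) {
    names(igraph::subcomponent(ig, v, mode = "in"))
  })))
  list(on_cycle = sort(on_cycle), affected = sort(affected))
}

stop_cycle <- function(on_cycle) {
  stop("composition cycle detected involving: ",
       paste(on_cycle, collapse = ", "), call. = FALSE)
}

## longest root-to-leaf path length for every node, NA for cycle-affected
node_depths <- function(edges, affected = NULL) {
  adj <- adjacency_list(edges)
  memo <- new.env(parent = emptyenv())
  depth_of <- function(iri) {
    if (!is.null(memo[[iri]])) return(memo[[iri]])
    kids <- adj[[iri]]
    d <- if (is.null(kids) || nrow(kids) == 0) {
      0L
    } else {
      1L + max(vapply(kids$to, depth_of, integer(1)))
    }
    memo[[iri]] <- d
    d
  }
  nodes <- unique(c(edges$from, edges$to))
  out <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (v in setdiff(nodes, affected)) out[[v]] <- depth_of(v)
  out
}

#' Classify every complex against the flat-composition rule
#'
#' BioPAX forbids a complex from containing another complex unless the
#' inner complex is a black box (its component list is empty). Each complex
#' therefore falls in exactly one category: `BLACK_BOX` (no components),
#' `VALID_NON_RECURSIVE` (has components, and every complex-typed component
#' is black-box), or `INVALID_RECURSIVE` (some component is a complex that
#' itself has components). Composition depth is the longest path from the
#' complex to any of its leaves: 0 for black-box complexes, 1 for valid
#' ones, 2 or more for invalid recursive ones.
#'
#' Complexes on or above a composition cycle cannot be classified; they get
#' `NA` category and depth and `on_cycle = TRUE`, and every other complex is
#' still processed.
#'
#' @param graph A `biopax_graph`.
#' @return A tibble with one row per complex: `iri`, `category`, `depth`,
#'   `n_direct` (direct component count), `on_cycle`.
#' @export
#' @examples
#' sim <- bp_simulate(fixture_config(seed = 1))
#' bp_classify(sim$graph) |> dplyr::count(category)
bp_classify <- function(graph) {
  stopifnot(inherits(graph, "biopax_graph"))
  edges <- bp_composition_edges(graph)
  cyc <- bp_cycles(edges)
  complexes <- graph$complexes$iri

  n_direct <- table(factor(edges$from, levels = complexes))
  n_direct <- stats::setNames(as.integer(n_direct), names(n_direct))

  ## a component is an "open" complex if it has components of its own
  open_complexes <- names(n_direct)[n_direct > 0]
  has_open_child <- vapply(complexes, function(cx) {
    kids <- edges$to[edges$from == cx]
    any(kids %in% open_complexes)
  }, logical(1))

  depths <- node_depths(edges, affected = cyc$affected)

  tibble::tibble(
    iri = complexes,
    category = dplyr::case_when(
      complexes %in% cyc$affected ~ NA_character_,
      n_direct[complexes] == 0L ~ "BLACK_BOX",
      has_open_child ~ "INVALID_RECURSIVE",
      TRUE ~ "VALID_NON_RECURSIVE"
    ),
    depth = dplyr::if_else(
      complexes %in% cyc$affected, NA_integer_,
      unname(dplyr::coalesce(depths[complexes], 0L))
    ),
    n_direct = unname(n_direct[complexes]),
    on_cycle = complexes %in% cyc$affected
  )
}

#' Composition depth of one complex
#'
#' @param graph A `biopax_graph`.
#' @param root Complex IRI.
#' @return Longest path length from `root` to any leaf (0 for black-box).
#' @export
bp_composition_depth <- function(graph, root) {
  edges <- bp_composition_edges(graph)
  cyc <- bp_cycles(edges)
  if (root %in% cyc$affected) stop_cycle(cyc$on_cycle)
  if (!root %in% graph$complexes$iri) {
    stop("'", root, "' is not a complex in this graph", call. = FALSE)
  }
  unname(node_depths(edges)[root] |> (\(d) if (is.na(d)) 0L else d)())
}

#' Census of complex categories
#'
#' Counts complexes per validity category. The three categories partition
#' the complex set: `BLACK_BOX + VALID_NON_RECURSIVE` are the valid
#' complexes, and all three sum to the total. Cycle-affected complexes (if
#' any) are reported under `CYCLIC`.
#'
#' @param graph A `biopax_graph`.
#' @return A tibble with columns `category`, `n`.
#' @export
bp_census <- function(graph) {
  cls <- bp_classify(graph)
  lev <- c("BLACK_BOX", "VALID_NON_RECURSIVE", "INVALID_RECURSIVE")
  cat <- ifelse(cls$on_cycle, "CYCLIC", cls$category)
  if (any(cls$on_cycle)) lev <- c(lev, "CYCLIC")
  tibble::tibble(category = factor(cat, levels = lev)) |>
    dplyr::count(.data$category, .drop = FALSE) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Interactions involving invalid complexes
#'
#' Counts the interactions whose participant set (the union over the
#' participation properties `left`, `right`, `controller`, `cofactor`,
#' `product`, `template` and `participant`, one hop only) intersects a set
#' of invalid complexes. Each interaction is counted once regardless of how
#' many invalid participants it has.
#'
#' @param graph A `biopax_graph`.
#' @param invalid Character vector of complex IRIs; defaults to the
#'   `INVALID_RECURSIVE` complexes of `graph`.
#' @return A tibble of the matching interactions (`interaction_iri`); the
#'   census count is its row count, with the total interaction count in
#'   attribute `n_total`.
#' @export
bp_interaction_census <- function(graph, invalid = NULL) {
  stopifnot(inherits(graph, "biopax_graph"))
  if (is.null(invalid)) {
    cls <- bp_classify(graph)
    invalid <- cls$iri[!is.na(cls$category) &
                         cls$category == "INVALID_RECURSIVE"]
  }
  out <- graph$interactions |>
    dplyr::filter(.data$participant_iri %in% invalid) |>
    dplyr::distinct(.data$interaction_iri)
  attr(out, "n_total") <- nrow(graph$interaction_iris)
  out
}
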