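## Redundant complexes: distinct records with exactly the same components,
## the same stoichiometric coefficients and the same cellular location.
## Signature equality is an equivalence relation, so the pair graph's
## connected components are cliques; this is verified, and grouping a pair
## set that is not transitively closed raises an internal-consistency error.

#' Canonical composition signatures
#'
#' One signature per complex with at least one direct component: the
#' order-independent multiset of (component IRI, coefficient) pairs plus
#' the cellular location (an explicit `"<absent>"` marker when missing —
#' location-less complexes only ever match each other). Black-box
#' complexes carry no composition evidence and are excluded.
#'
#' @param graph A `biopax_graph`.
#' @param ignore_location Drop the cellular-location part of the signature.
#' @param coef_digits Optional number of significant digits to round
#'   coefficients to before comparison; default compares exactly as stored.
#' @return A tibble: `iri`, `signature`, `cellular_location`, `n_components`.
#' @export
bp_signatures <- function(graph, ignore_location = FALSE,
                          coef_digits = NULL) {
  stopifnot(inherits(graph, "biopax_graph"))
  comp <- graph$components
  if (!is.null(coef_digits)) {
    comp$coefficient <- signif(comp$coefficient, coef_digits)
  }
  sig <- comp |>
    dplyr::arrange(.data$complex_iri, .data$component_iri) |>
    dplyr::group_by(iri = .data$complex_iri) |>
    dplyr::summarise(
      parts = paste0(.data$component_iri, "×",
                     format_coefficient(.data$coefficient),
                     collapse = "|"),
      n_components = dplyr::n(),
      .groups = "drop"
    )
  sig <- sig |>
    dplyr::left_join(graph$complexes, by = "iri") |>
    dplyr::mutate(
      loc = dplyr::coalesce(.data$cellular_location, "<absent>"),
      signature = if (ignore_location) .data$parts
                  else paste0(.data$parts, "@", .data$loc)
    ) |>
    dplyr::select("iri", "signature", "cellular_location", "n_components")
  sig
}

#' Find redundant complex pairs
#'
#' All unordered pairs of distinct complexes with equal composition
#' signatures. Typically run after [bp_fix_all()]: flattening reveals
#' redundancies that different recursive nestings of the same composition
#' would otherwise hide.
#'
#' @inheritParams bp_signatures
#' @return A tibble of unordered pairs: `iri_a`, `iri_b` (with
#'   `iri_a < iri_b`), `signature`.
#' @export
bp_redundant_pairs <- function(graph, ignore_location = FALSE,
                               coef_digits = NULL) {
  sig <- bp_signatures(graph, ignore_location, coef_digits)
  dup <- sig |>
    dplyr::group_by(.data$signature) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
  if (nrow(dup) == 0) {
    return(tibble::tibble(iri_a = character(0), iri_b = character(0),
                          signature = character(0)))
  }
  dup |>
    dplyr::group_by(.data$signature) |>
    dplyr::reframe({
      m <- sort(.data$iri)
      pr <- t(utils::combn(m, 2))
      tibble::tibble(iri_a = pr[, 1], iri_b = pr[, 2])
    }) |>
    dplyr::select("iri_a", "iri_b", "signature") |>
    dplyr::arrange(.data$iri_a, .data$iri_b)
}

#' Group redundant pairs into maximal cliques
#'
#' Because signature equality is transitive, every connected component of
#' the pair graph must itself be a maximal clique; this is verified and a
#' violation (which would indicate a signature-comparison bug upstream)
#' raises an internal-consistency error. For a group of size k the derived
#' quantities are `n_pairs = k(k-1)/2` and `excess = k-1` (the records
#' beyond one canonical representative).
#'
#' @param pairs A pair tibble from [bp_redundant_pairs()] (columns `iri_a`,
#'   `iri_b`, optionally `signature`).
#' @return A tibble: `group_id`, `size`, `n_pairs`, `excess`, `members`
#'   (list-column of IRIs), `signature` (if supplied).
#' @export
bp_group_pairs <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(group_id = integer(0), size = integer(0),
                          n_pairs = integer(0), excess = integer(0),
                          members = list(), signature = character(0)))
  }
  ig <- igraph::graph_from_data_frame(pairs[c("iri_a", "iri_b")],
                                      directed = FALSE)
  comp <- igraph::components(ig)
  membership <- comp$membership
  edge_group <- membership[pairs$iri_a]
  groups <- tibble::tibble(iri = names(membership),
                           group_id = unname(membership)) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(size = dplyr::n(),
                     members = list(sort(.data$iri)), .groups = "drop")
  n_edges <- table(factor(edge_group, levels = groups$group_id))
  expected <- groups$size * (groups$size - 1) / 2
  bad <- which(as.integer(n_edges) != expected)
  if (length(bad)) {
    stop("internal-consistency error: redundancy component(s) ",
         paste(groups$group_id[bad], collapse = ", "),
         " are not cliques; signature comparison is not transitive",
         call. = FALSE)
  }
  sig_col <- if ("signature" %in% names(pairs)) {
    vapply(groups$members,
           function(m) pairs$signature[pairs$iri_a == m[[1]]][[1]],
           character(1))
  } else {
    NA_character_
  }
  groups |>
    dplyr::mutate(
      group_id = dplyr::row_number(),
      n_pairs = as.integer(.data$size * (.data$size - 1) / 2),
      excess = .data$size - 1L,
      signature = sig_col
    ) |>
    dplyr::select("group_id", "size", "n_pairs", "excess", "members",
                  "signature")
}

#' Detect redundant complexes
#'
#' Runs signature computation, pair detection and clique grouping in one
#' step and keeps the accounting together: `n_pairs` (sum of k(k-1)/2 over
#' groups), `n_groups` (maximal cliques), `n_distinct` (complexes involved)
#' and `n_excess = n_distinct - n_groups` (records beyond one
#' representative per group).
#'
#' @inheritParams bp_signatures
#' @return An object of class `bp_redundancy` with elements `pairs`,
#'   `groups` and the four totals; `tidy()` returns the groups, `glance()`
#'   the totals.
#' @export
#' @examples
#' sim <- bp_simulate(fixture_config(seed = 1, n_redundant_groups = 2))
#' red <- bp_redundancy(bp_fix_all(sim$graph)$graph)
#' glance(red)
bp_redundancy <- function(graph, ignore_location = FALSE,
                          coef_digits = NULL) {
  pairs <- bp_redundant_pairs(graph, ignore_location, coef_digits)
  groups <- bp_group_pairs(pairs)
  structure(
    list(
      pairs = pairs,
      groups = groups,
      n_pairs = nrow(pairs),
      n_groups = nrow(groups),
      n_distinct = sum(groups$size),
      n_excess = sum(groups$excess)
    ),
    class = "bp_redundancy"
  )
}

#' @method tidy bp_redundancy
#' @export
tidy.bp_redundancy <- function(x, ...) x$groups

#' @method glance bp_redundancy
#' @export
glance.bp_redundancy <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_groups = x$n_groups,
                 n_distinct = x$n_distinct, n_excess = x$n_excess)
}

#' @export
print.bp_redundancy <- function(x, ...) {
  cat("<bp_redundancy>", x$n_pairs, "pairs in", x$n_groups,
      "maximal cliques;", x$n_distinct, "distinct complexes,",
      x$n_excess, "in excess\n")
  invisible(x)
}

#' @rdname autoplot-complexfix
#' @method autoplot bp_redundancy
#' @export
autoplot.bp_redundancy <- function(object, ...) {
  ggplot2::ggplot(object$groups, ggplot2::aes(x = factor(.data$size))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "clique size (complexes per redundancy group)",
                  y = "number of groups") +
    ggplot2::theme_minimal()
}

#' Annotate redundancy groups in the graph
#'
#' Adds a symmetric `hasSameCompositionAs` statement (in a dedicated
#' annotation namespace, leaving all original BioPAX statements untouched)
#' for every ordered pair within each redundancy group: a group of size k
#' yields k(k-1) directed statements.
#'
#' @param graph A `biopax_graph`.
#' @param redundancy A `bp_redundancy` object (or a groups tibble from
#'   [bp_group_pairs()]).
#' @return The annotated `biopax_graph`.
#' @export
bp_annotate_same_composition <- function(graph, redundancy) {
  stopifnot(inherits(graph, "biopax_graph"))
  groups <- if (inherits(redundancy, "bp_redundancy")) {
    redundancy$groups
  } else {
    redundancy
  }
  if (nrow(groups) == 0) return(graph)
  pred <- paste0(NS_CFX, "hasSameCompositionAs")
  new_triples <- dplyr::bind_rows(lapply(groups$members, function(m) {
    grid <- expand.grid(a = m, b = m, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, ]
    triple(grid$a, pred, grid$b)
  }))
  graph$residual <- sort_triples(
    dplyr::distinct(dplyr::bind_rows(graph$residual, new_triples)))
  graph
}
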