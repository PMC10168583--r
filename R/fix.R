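## Flattening invalid recursive complexes.
##
## The global stoichiometric coefficient S_y(z) — the number of occurrences
## of entity z in complex y — satisfies
##   S_z(z) = 1
##   S_y(z) = 0                       if y != z and y has no components
##   S_y(z) = sum_{p in C(y)} c_y(p) * S_p(z)   otherwise,
## with c_y(p) the direct-edge coefficient. Equivalently, S_y(z) is the sum
## over all y->z composition paths of the product of edge coefficients
## along each path. Computed here as a memoized dynamic program over the
## composition DAG, so shared sub-complexes (diamonds) are visited once.

## memoized flattening: named numeric vector leaf -> S_root(leaf), plus a
## parallel logical vector marking leaves whose coefficient involves at
## least one defaulted (explicit = FALSE) edge
flatten_root <- function(root, adj, memo) {
  key <- root
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  kids <- adj[[root]]
  res <- if (is.null(kids) || nrow(kids) == 0) {
    list(coef = stats::setNames(1, root),
         defaulted = stats::setNames(FALSE, root))
  } else {
    coef <- numeric(0)
    defaulted <- logical(0)
    for (k in seq_len(nrow(kids))) {
      sub <- flatten_root(kids$to[[k]], adj, memo)
      contrib <- kids$coefficient[[k]] * sub$coef
      dflag <- (!kids$explicit[[k]]) | sub$defaulted
      for (leaf in names(contrib)) {
        coef[leaf] <- sum(coef[leaf], contrib[[leaf]], na.rm = TRUE)
        defaulted[leaf] <- isTRUE(defaulted[leaf]) | dflag[[leaf]]
      }
    }
    list(coef = coef, defaulted = defaulted)
  }
  memo[[key]] <- res
  res
}

check_acyclic_at <- function(graph, root) {
  cyc <- bp_cycles(graph)
  if (root %in% cyc$affected) stop_cycle(cyc$on_cycle)
}

#' Leaves of a complex's composition tree
#'
#' The entities reachable from `root` that have no composition edges of
#' their own: non-complex physical entities and black-box complexes. These
#' are the components a conformant flat representation must list directly.
#' A black-box root has no components, hence no leaves.
#'
#' @param graph A `biopax_graph`.
#' @param root Complex IRI.
#' @return Character vector of leaf IRIs (sorted).
#' @export
bp_leaves <- function(graph, root) {
  stopifnot(inherits(graph, "biopax_graph"))
  if (!root %in% graph$complexes$iri) {
    stop("'", root, "' is not a complex in this graph", call. = FALSE)
  }
  check_acyclic_at(graph, root)
  edges <- bp_composition_edges(graph)
  if (!root %in% edges$from) return(character(0))
  adj <- adjacency_list(edges)
  memo <- new.env(parent = emptyenv())
  sort(names(flatten_root(root, adj, memo)$coef))
}

#' Global stoichiometric coefficient
#'
#' Number of occurrences of `leaf` in `root`, summing the product of edge
#' coefficients over every composition path from root to leaf (memoized
#' dynamic program over the DAG). `S_z(z) = 1` for any entity.
#'
#' @param graph A `biopax_graph`.
#' @param root Complex IRI.
#' @param leaf Leaf entity IRI; if `NULL`, the full flattening is returned.
#' @return A single positive number, or (for `leaf = NULL`) a tibble with
#'   columns `leaf`, `coefficient`, `any_defaulted`.
#' @export
#' @examples
#' # X contains 2 Y and directly 1 Z; Y contains 3 Z  =>  S_X(Z) = 2*3 + 1
#' g <- bp_graph(
#'   tibble::tibble(iri = c("cx:X", "cx:Y", "cx:Z"),
#'                  kind = c("complex", "complex", "protein")),
#'   tibble::tibble(complex_iri = c("cx:X", "cx:X", "cx:Y"),
#'                  component_iri = c("cx:Y", "cx:Z", "cx:Z"),
#'                  coefficient = c(2, 1, 3))
#' )
#' bp_global_stoichiometry(g, "cx:X", "cx:Z")  # 7
bp_global_stoichiometry <- function(graph, root, leaf = NULL) {
  stopifnot(inherits(graph, "biopax_graph"))
  check_acyclic_at(graph, root)
  edges <- bp_composition_edges(graph)
  if (!is.null(leaf) && identical(root, leaf)) return(1)
  if (!root %in% edges$from) {
    if (is.null(leaf)) {
      return(tibble::tibble(leaf = character(0), coefficient = numeric(0),
                            any_defaulted = logical(0)))
    }
    stop("'", leaf, "' is not reachable from '", root, "'", call. = FALSE)
  }
  adj <- adjacency_list(edges)
  memo <- new.env(parent = emptyenv())
  res <- flatten_root(root, adj, memo)
  if (is.null(leaf)) {
    ord <- order(names(res$coef))
    return(tibble::tibble(leaf = names(res$coef)[ord],
                          coefficient = unname(res$coef)[ord],
                          any_defaulted = unname(res$defaulted)[ord]))
  }
  if (!leaf %in% names(res$coef)) {
    stop("'", leaf, "' is not reachable from '", root, "'", call. = FALSE)
  }
  unname(res$coef[[leaf]])
}

## flatten a set of roots against the *original* topology and rewrite their
## direct components; shared by bp_fix and bp_fix_all
apply_flatten <- function(graph, roots) {
  edges <- bp_composition_edges(graph)
  adj <- adjacency_list(edges)
  memo <- new.env(parent = emptyenv())
  new_rows <- lapply(roots, function(root) {
    res <- flatten_root(root, adj, memo)
    ord <- order(names(res$coef))
    tibble::tibble(
      complex_iri = root,
      component_iri = names(res$coef)[ord],
      coefficient = unname(res$coef)[ord],
      explicit = TRUE,
      stoich_iri = NA_character_
    )
  })
  graph$components <- dplyr::bind_rows(
    graph$components[!graph$components$complex_iri %in% roots, ],
    dplyr::bind_rows(new_rows)
  ) |>
    dplyr::arrange(.data$complex_iri, .data$component_iri)
  graph
}

#' Flatten one invalid recursive complex
#'
#' Rewrites `root`'s direct components to be exactly the leaves of its
#' composition tree, each with its global stoichiometric coefficient; all
#' edges from `root` to intermediate complexes are removed. The
#' intermediate complexes themselves stay in the graph (they may
#' participate elsewhere), and every non-component statement about `root`
#' is untouched. Fixing a complex that is not invalid is a no-op with a
#' warning.
#'
#' @param graph A `biopax_graph`.
#' @param root Complex IRI classified `INVALID_RECURSIVE`.
#' @return The modified `biopax_graph`.
#' @export
bp_fix_complex <- function(graph, root) {
  stopifnot(inherits(graph, "biopax_graph"))
  check_acyclic_at(graph, root)
  cls <- bp_classify(graph)
  cat <- cls$category[cls$iri == root]
  if (!length(cat)) {
    stop("'", root, "' is not a complex in this graph", call. = FALSE)
  }
  if (!identical(cat, "INVALID_RECURSIVE")) {
    warning("'", root, "' is not an invalid recursive complex; nothing to fix")
    return(graph)
  }
  apply_flatten(graph, root)
}

#' Fix all invalid recursive complexes
#'
#' Flattens every `INVALID_RECURSIVE` complex (each against the original
#' topology, so fixing order is irrelevant) and reports per-complex
#' before/after bookkeeping. Afterwards every complex has composition
#' depth 0 or 1 and re-running the operation is the identity.
#'
#' @param graph A `biopax_graph`.
#' @param on_cycle `"error"` (default) aborts when invalid complexes sit on
#'   or above a composition cycle, naming them; `"skip"` fixes the rest and
#'   lists the unfixable ones in the result.
#' @return An object of class `bp_fix` with elements `graph` (the fixed
#'   graph), `report` (per-complex tibble: `iri`, `category_before`,
#'   `depth_before`, `n_components_before`, `n_components_after`,
#'   `n_defaulted_coefficients`, `composition` list-column of
#'   leaf/coefficient tibbles), `skipped` (cycle-affected IRIs) and totals.
#'   Use [generics::tidy()] / [generics::glance()] to extract them.
#' @export
#' @examples
#' sim <- bp_simulate(fixture_config(seed = 1))
#' fx <- bp_fix_all(sim$graph)
#' glance(fx)
bp_fix_all <- function(graph, on_cycle = c("error", "skip")) {
  stopifnot(inherits(graph, "biopax_graph"))
  on_cycle <- match.arg(on_cycle)
  cyc <- bp_cycles(graph)
  if (length(cyc$affected) && on_cycle == "error") {
    stop("cannot fix: composition cycle leaves these complexes unfixable: ",
         paste(intersect(cyc$affected, graph$complexes$iri),
               collapse = ", "), call. = FALSE)
  }
  before <- bp_classify(graph)
  roots <- before$iri[!is.na(before$category) &
                        before$category == "INVALID_RECURSIVE"]
  fixed <- apply_flatten(graph, roots)

  after_counts <- table(factor(fixed$components$complex_iri,
                               levels = before$iri))
  edges <- bp_composition_edges(graph)
  adj <- adjacency_list(edges)
  memo <- new.env(parent = emptyenv())
  composition <- lapply(before$iri, function(cx) {
    if (cx %in% cyc$affected) {
      return(tibble::tibble(leaf = character(0), coefficient = numeric(0),
                            any_defaulted = logical(0)))
    }
    if (!cx %in% edges$from) {
      return(tibble::tibble(leaf = character(0), coefficient = numeric(0),
                            any_defaulted = logical(0)))
    }
    res <- flatten_root(cx, adj, memo)
    ord <- order(names(res$coef))
    tibble::tibble(leaf = names(res$coef)[ord],
                   coefficient = unname(res$coef)[ord],
                   any_defaulted = unname(res$defaulted)[ord])
  })
  report <- tibble::tibble(
    iri = before$iri,
    category_before = before$category,
    depth_before = before$depth,
    n_components_before = before$n_direct,
    n_components_after = as.integer(after_counts[before$iri]),
    n_defaulted_coefficients = vapply(
      composition, function(tb) sum(tb$any_defaulted), integer(1)),
    composition = composition
  )
  structure(
    list(
      graph = fixed,
      report = report,
      skipped = intersect(cyc$affected, graph$complexes$iri),
      n_fixed = length(roots),
      n_unchanged = nrow(before) - length(roots)
    ),
    class = "bp_fix"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy bp_fix
#' @export
tidy.bp_fix <- function(x, ...) x$report

#' @method glance bp_fix
#' @export
glance.bp_fix <- function(x, ...) {
  after <- bp_classify(x$graph)
  tibble::tibble(
    n_complexes = nrow(x$report),
    n_fixed = x$n_fixed,
    n_unchanged = x$n_unchanged,
    n_skipped_cyclic = length(x$skipped),
    mean_components_before = mean(x$report$n_components_before),
    mean_components_after = mean(x$report$n_components_after),
    max_depth_before = max(c(0L, x$report$depth_before), na.rm = TRUE),
    max_depth_after = max(c(0L, after$depth), na.rm = TRUE)
  )
}

#' @export
print.bp_fix <- function(x, ...) {
  cat("<bp_fix> flattened", x$n_fixed, "invalid recursive complexes;",
      x$n_unchanged, "unchanged")
  if (length(x$skipped)) cat(";", length(x$skipped), "skipped (cyclic)")
  cat("\n")
  invisible(x)
}

#' @rdname autoplot-complexfix
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plots of complexfix results
#'
#' `autoplot.bp_fix` shows per-complex direct-component counts before vs
#' after flattening; `autoplot.bp_redundancy` the redundancy-group size
#' distribution; `autoplot.bp_report` the before/after composition-depth
#' histograms.
#'
#' @param object A `bp_fix`, `bp_redundancy` or `bp_report` object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-complexfix
NULL

#' @rdname autoplot-complexfix
#' @method autoplot bp_fix
#' @export
autoplot.bp_fix <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$n_components_before,
                               y = .data$n_components_after,
                               colour = .data$category_before)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_count(alpha = 0.7) +
    ggplot2::labs(x = "direct components before fixing",
                  y = "direct components after fixing",
                  colour = "category") +
    ggplot2::theme_minimal()
}
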