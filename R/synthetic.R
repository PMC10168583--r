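## Synthetic BioPAX fixtures with known ground truth.
##
## The generator emulates the structures found in curated pathway exports:
## nested complex composition trees and DAGs (shared sub-complexes reachable
## by multiple paths), per-edge stoichiometric coefficients, black-box
## complexes, cellular locations, interaction stubs, and planted redundancy
## groups realised as different binary re-bracketings of one flat component
## multiset at one location. Ground truth (categories, depths, flattened
## compositions, redundancy groups) is computed by direct recursion and
## exhaustive path enumeration, independent of the analysis modules.

FIXTURE_NS <- "http://example.org/complexfix-fixtures#"
fx_iri <- function(local) paste0(FIXTURE_NS, local)

#' Fixture generator configuration
#'
#' Defaults describe a small but structurally rich pathway export: a few
#' dozen entities, nesting several levels deep, occasional black boxes and
#' shared sub-complexes, small integer coefficients, and one planted
#' redundancy group.
#'
#' @param n_atomic Number of atomic (non-complex) physical entities.
#' @param n_complexes Number of complexes (planted redundancy-group members
#'   and the depth-realising chain count against this budget; the inner
#'   bracketing complexes of planted groups are extra).
#' @param max_depth Target nesting depth: at least one complex attains
#'   exactly this composition depth.
#' @param branching Integer range (min, max) of children per non-black-box
#'   complex.
#' @param coefficient_range Integer range for edge stoichiometric
#'   coefficients.
#' @param p_blackbox Probability a complex is a black box (no components).
#' @param p_shared Probability a child slot is filled by an existing
#'   complex rather than an atomic entity (creates diamonds).
#' @param n_redundant_groups Number of planted redundancy groups.
#' @param group_size_range Integer range for planted group sizes.
#' @param n_locations Number of distinct cellular locations.
#' @param p_no_location Probability a complex has no location annotation.
#' @param n_interactions Number of interaction stubs.
#' @param seed Random seed; generation is a pure function of the config.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_atomic = 25, n_complexes = 15, max_depth = 4,
                           branching = c(2, 4), coefficient_range = c(1, 5),
                           p_blackbox = 0.1, p_shared = 0.25,
                           n_redundant_groups = 1,
                           group_size_range = c(2, 3), n_locations = 3,
                           p_no_location = 0.15, n_interactions = 5,
                           seed = 1) {
  cfg <- list(
    n_atomic = n_atomic, n_complexes = n_complexes, max_depth = max_depth,
    branching = as.integer(branching),
    coefficient_range = as.integer(coefficient_range),
    p_blackbox = p_blackbox, p_shared = p_shared,
    n_redundant_groups = n_redundant_groups,
    group_size_range = as.integer(group_size_range),
    n_locations = n_locations, p_no_location = p_no_location,
    n_interactions = n_interactions, seed = as.integer(seed)
  )
  probs <- c(p_blackbox, p_shared, p_no_location)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(n_atomic, n_complexes, max_depth, n_redundant_groups,
              n_locations, n_interactions)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  reserved <- n_redundant_groups * max(group_size_range) +
    min(max_depth, 1) * max_depth
  if (reserved > n_complexes) {
    stop("infeasible config: ", reserved, " complexes needed for planted ",
         "groups and the depth chain, but n_complexes = ", n_complexes,
         call. = FALSE)
  }
  if (n_redundant_groups > 0 && n_atomic < 4) {
    stop("infeasible config: planted redundancy groups need >= 4 atomic ",
         "entities", call. = FALSE)
  }
  structure(cfg, class = "fixture_config")
}

## run expr under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Exhaustive composition expansion (reference oracle)
#'
#' Unrolls the composition tree below `root` without memoization,
#' multiplying coefficients down every root-to-leaf path and summing per
#' leaf. Exponential in the worst case; intended as an independent check
#' of the dynamic program on small graphs. An atomic (childless) root
#' expands to itself with count 1.
#'
#' @param graph A `biopax_graph` or a composition-edge tibble
#'   (`from`, `to`, `coefficient`).
#' @param root Entity IRI.
#' @return A tibble `leaf`, `count`, sorted by leaf.
#' @export
bp_expand_brute_force <- function(graph, root) {
  edges <- if (inherits(graph, "biopax_graph")) {
    bp_composition_edges(graph)
  } else {
    tibble::as_tibble(graph)
  }
  counts <- new.env(parent = emptyenv())
  walk <- function(node, product, path) {
    if (node %in% path) {
      stop_cycle(c(path[match(node, path):length(path)], node))
    }
    kids <- which(edges$from == node)
    if (!length(kids)) {
      counts[[node]] <- sum(counts[[node]], product)
      return(invisible())
    }
    for (k in kids) {
      walk(edges$to[[k]], product * edges$coefficient[[k]],
           c(path, node))
    }
  }
  walk(root, 1, character(0))
  leaves <- sort(ls(counts))
  tibble::tibble(
    leaf = leaves,
    count = vapply(leaves, function(l) counts[[l]], numeric(1),
                   USE.NAMES = FALSE))
}

## independent category/depth recursion used for ground truth
truth_category <- function(cx, children) {
  kids <- children[[cx]]
  if (is.null(kids) || nrow(kids) == 0) return("BLACK_BOX")
  open_child <- any(vapply(kids$to, function(k) {
    kk <- children[[k]]
    !is.null(kk) && nrow(kk) > 0
  }, logical(1)))
  if (open_child) "INVALID_RECURSIVE" else "VALID_NON_RECURSIVE"
}

truth_depth <- function(node, children) {
  kids <- children[[node]]
  if (is.null(kids) || nrow(kids) == 0) return(0L)
  1L + max(vapply(kids$to, truth_depth, integer(1), children = children))
}

## random binary bracketing of a flat multiset of (atom, coefficient):
## inner edges carry coefficient 1, each atom's unique leaf edge carries
## its target coefficient, so the flattened composition equals the target
bracket_complex <- function(root_iri, atoms, coefs, state) {
  build <- function(parent, idx) {
    if (length(idx) == 1) {
      state$edges[[length(state$edges) + 1L]] <- tibble::tibble(
        complex_iri = parent, component_iri = atoms[[idx]],
        coefficient = coefs[[idx]])
      return(invisible())
    }
    cut <- sample(seq_len(length(idx) - 1), 1)
    halves <- list(idx[seq_len(cut)], idx[-seq_len(cut)])
    for (half in halves) {
      if (length(half) == 1) {
        build(parent, half)
      } else {
        state$n_sub <- state$n_sub + 1L
        sub <- fx_iri(sprintf("SUB%03d", state$n_sub))
        state$subs <- c(state$subs, sub)
        state$edges[[length(state$edges) + 1L]] <- tibble::tibble(
          complex_iri = parent, component_iri = sub, coefficient = 1)
        build(sub, half)
      }
    }
  }
  build(root_iri, seq_along(atoms))
}

#' Generate a synthetic BioPAX fixture with ground truth
#'
#' @param config A [fixture_config()].
#' @return A list with `graph` (a `biopax_graph`) and `truth`: a list with
#'   `complexes` (tibble `iri`, `category`, `depth`, `flat` list-column of
#'   leaf/count tibbles from [bp_expand_brute_force()]) and `groups`
#'   (redundancy groups derived from the oracle flattening plus location).
#' @export
#' @examples
#' sim <- bp_simulate(fixture_config(seed = 42))
#' sim$graph
#' dplyr::count(sim$truth$complexes, category)
bp_simulate <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    atom_kinds <- c("protein", "small-molecule", "rna", "dna")
    atoms <- if (config$n_atomic > 0) {
      tibble::tibble(
        iri = fx_iri(sprintf("A%03d", seq_len(config$n_atomic))),
        kind = sample(atom_kinds, config$n_atomic, replace = TRUE,
                      prob = c(0.6, 0.25, 0.1, 0.05)),
        display_name = sprintf("atom %03d", seq_len(config$n_atomic))
      )
    } else {
      tibble::tibble(iri = character(0), kind = character(0),
                     display_name = character(0))
    }
    locations <- if (config$n_locations > 0) {
      fx_iri(sprintf("LOC%02d", seq_len(config$n_locations)))
    } else {
      character(0)
    }
    ## sample n values from an integer range; safe for degenerate ranges
    ## (sample() would misread a scalar as 1:x)
    pick_range <- function(range, n = 1) {
      v <- seq(range[[1]], range[[2]])
      v[sample.int(length(v), n, replace = TRUE)]
    }
    rcoef <- function(n = 1) pick_range(config$coefficient_range, n)

    cx_iris <- if (config$n_complexes > 0) {
      fx_iri(sprintf("CX%03d", seq_len(config$n_complexes)))
    } else {
      character(0)
    }
    edge_rows <- list()
    extra_subs <- character(0)
    n_sub <- 0L
    depth_of <- stats::setNames(rep(0L, nrow(atoms)), atoms$iri)
    cx_loc <- stats::setNames(rep(NA_character_, length(cx_iris)), cx_iris)

    i <- 0L
    take_cx <- function() {
      i <<- i + 1L
      if (i > length(cx_iris)) stop("internal: complex budget exhausted")
      cx_iris[[i]]
    }

    ## (1) a chain realising the target depth exactly
    chain_len <- min(config$max_depth, config$n_complexes)
    chain <- character(0)
    if (chain_len > 0 && nrow(atoms) > 0) {
      for (lvl in seq_len(chain_len)) {
        cx <- take_cx()
        kids <- if (lvl == 1) {
          sample(atoms$iri, min(2, nrow(atoms)))
        } else {
          c(chain[[lvl - 1]], sample(atoms$iri, 1))
        }
        edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
          complex_iri = cx, component_iri = unique(kids),
          coefficient = rcoef(length(unique(kids))))
        depth_of[[cx]] <- lvl
        chain <- c(chain, cx)
      }
    }

    ## (2) planted redundancy groups: same flat multiset, same location,
    ## different random bracketings
    planted <- list()
    if (config$n_redundant_groups > 0) {
      state <- new.env(parent = emptyenv())
      state$edges <- list()
      state$subs <- character(0)
      state$n_sub <- 0L
      for (gidx in seq_len(config$n_redundant_groups)) {
        k <- pick_range(config$group_size_range)
        n_leaves <- sample(3:4, 1)
        leaf_atoms <- sample(atoms$iri, n_leaves)
        leaf_coefs <- rcoef(n_leaves)
        loc <- if (length(locations)) sample(locations, 1) else NA_character_
        members <- character(0)
        for (m in seq_len(k)) {
          cx <- take_cx()
          bracket_complex(cx, leaf_atoms, leaf_coefs, state)
          cx_loc[[cx]] <- loc
          members <- c(members, cx)
        }
        planted[[gidx]] <- list(members = members, location = loc)
      }
      edge_rows <- c(edge_rows, state$edges)
      extra_subs <- state$subs
      n_sub <- state$n_sub
      ## bracketing nests at most ceiling(log2(n_leaves)) + 1 deep; well
      ## under max_depth for the leaf counts used here
    }

    ## (3) remaining complexes: black boxes and random compositions over
    ## atoms and existing complexes shallower than max_depth
    while (i < length(cx_iris)) {
      cx <- take_cx()
      if (stats::runif(1) < config$p_blackbox || nrow(atoms) == 0) {
        depth_of[[cx]] <- 0L
        next
      }
      n_kids <- pick_range(config$branching)
      sharable <- names(depth_of)[depth_of > 0 &
                                    depth_of < config$max_depth]
      kids <- vapply(seq_len(n_kids), function(j) {
        if (length(sharable) && stats::runif(1) < config$p_shared) {
          sample(sharable, 1)
        } else {
          sample(atoms$iri, 1)
        }
      }, character(1))
      kids <- unique(kids)
      edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
        complex_iri = cx, component_iri = kids,
        coefficient = rcoef(length(kids)))
      depth_of[[cx]] <- 1L + max(depth_of[kids])
      if (length(locations) && stats::runif(1) > config$p_no_location) {
        cx_loc[[cx]] <- sample(locations, 1)
      }
    }

    all_cx <- c(cx_iris, extra_subs)
    entities <- dplyr::bind_rows(
      atoms,
      tibble::tibble(iri = all_cx, kind = "complex",
                     display_name = sub(FIXTURE_NS, "", all_cx, fixed = TRUE))
    )
    components <- if (length(edge_rows)) {
      dplyr::bind_rows(edge_rows) |>
        dplyr::mutate(coefficient = as.numeric(.data$coefficient)) |>
        dplyr::group_by(.data$complex_iri, .data$component_iri) |>
        dplyr::summarise(coefficient = sum(.data$coefficient),
                         .groups = "drop")
    } else {
      NULL
    }
    loc_tbl <- tibble::tibble(complex_iri = names(cx_loc),
                              location_iri = unname(cx_loc)) |>
      dplyr::filter(!is.na(.data$location_iri))
    interactions <- if (config$n_interactions > 0 && nrow(entities) > 0) {
      dplyr::bind_rows(lapply(seq_len(config$n_interactions), function(j) {
        parts <- sample(entities$iri, sample(1:3, 1))
        tibble::tibble(
          interaction_iri = fx_iri(sprintf("RX%03d", j)),
          participant_iri = parts,
          property = sample(c("left", "right", "participant"),
                            length(parts), replace = TRUE))
      }))
    } else {
      NULL
    }
    graph <- bp_graph(entities, components,
                      if (nrow(loc_tbl)) loc_tbl else NULL, interactions)

    ## ground truth by independent recursion + exhaustive expansion
    edges <- if (is.null(components)) {
      tibble::tibble(from = character(0), to = character(0),
                     coefficient = numeric(0))
    } else {
      dplyr::transmute(components, from = .data$complex_iri,
                       to = .data$component_iri,
                       coefficient = .data$coefficient)
    }
    children <- split(tibble::tibble(to = edges$to,
                                     coefficient = edges$coefficient),
                      edges$from)
    truth_cx <- tibble::tibble(
      iri = sort(all_cx),
      category = vapply(sort(all_cx), truth_category, character(1),
                        children = children, USE.NAMES = FALSE),
      depth = vapply(sort(all_cx), truth_depth, integer(1),
                     children = children, USE.NAMES = FALSE),
      flat = lapply(sort(all_cx), function(cx) {
        if (is.null(children[[cx]]) || nrow(children[[cx]]) == 0) {
          tibble::tibble(leaf = character(0), count = numeric(0))
        } else {
          bp_expand_brute_force(edges, cx)
        }
      })
    )
    ## redundancy ground truth: oracle flattening + location
    flat_sig <- vapply(seq_len(nrow(truth_cx)), function(k) {
      fl <- truth_cx$flat[[k]]
      if (nrow(fl) == 0) return(NA_character_)
      loc <- graph$complexes$cellular_location[
        graph$complexes$iri == truth_cx$iri[[k]]]
      paste0(paste0(fl$leaf, "×", format_coefficient(fl$count),
                    collapse = "|"),
             "@", dplyr::coalesce(loc, "<absent>"))
    }, character(1))
    sig_groups <- split(truth_cx$iri, flat_sig)
    sig_groups <- sig_groups[vapply(sig_groups, length, integer(1)) >= 2]
    truth_groups <- tibble::tibble(
      members = unname(lapply(sig_groups, sort)),
      size = vapply(sig_groups, length, integer(1))
    )
    list(
      graph = graph,
      truth = list(
        complexes = truth_cx,
        groups = truth_groups,
        planted = planted,
        max_depth = if (nrow(truth_cx)) max(truth_cx$depth) else 0L
      )
    )
  })
}
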