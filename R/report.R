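#' Direct-component count statistics
#'
#' Mean, population standard deviation (divisor n) and maximum of the
#' direct-component counts over all complexes, black boxes included (they
#' contribute 0). `argmax` lists every complex attaining the maximum.
#'
#' @param graph A `biopax_graph`.
#' @return One-row tibble: `n_complexes`, `mean`, `sd`, `max`, `argmax`
#'   (list-column of IRIs).
#' @export
bp_component_stats <- function(graph) {
  stopifnot(inherits(graph, "biopax_graph"))
  cx <- graph$complexes$iri
  if (!length(cx)) {
    stop("undefined statistics: the graph contains no complexes",
         call. = FALSE)
  }
  counts <- table(factor(graph$components$complex_iri, levels = cx))
  counts <- stats::setNames(as.integer(counts), names(counts))
  mu <- mean(counts)
  sd_pop <- sqrt(mean((counts - mu)^2))
  mx <- max(counts)
  tibble::tibble(
    n_complexes = length(cx),
    mean = mu,
    sd = sd_pop,
    max = mx,
    argmax = list(sort(names(counts)[counts == mx]))
  )
}

#' Composition-depth histogram
#'
#' Count of complexes per composition depth. After [bp_fix_all()] the
#' support is contained in {0, 1}. Errors if the composition graph has a
#' cycle (depth is undefined there).
#'
#' @param graph A `biopax_graph`.
#' @return Tibble `depth`, `n`, sorted by depth.
#' @export
bp_depth_histogram <- function(graph) {
  cls <- bp_classify(graph)
  if (any(cls$on_cycle)) {
    stop_cycle(cls$iri[cls$on_cycle])
  }
  cls |>
    dplyr::count(depth = .data$depth) |>
    dplyr::arrange(.data$depth)
}

#' Before/after summary report
#'
#' The full accounting of a fixing run, in the layout of a per-organism
#' summary table: census and invalid percentage, direct-component
#' statistics and depth histograms before and after, and redundancy
#' accounting (pairs, maximal cliques, distinct members, excess) before
#' and after. Percentages and means are kept at full precision; `print()`
#' rounds for display (means to 1 decimal, percentages to integers).
#'
#' @param before A `biopax_graph` (as loaded).
#' @param after The corresponding fixed graph, e.g. `bp_fix_all(before)$graph`.
#' @return An object of class `bp_report`; `glance()` returns the one-row
#'   wide summary, `tidy()` a long metric/before/after table.
#' @export
#' @examples
#' sim <- bp_simulate(fixture_config(seed = 7))
#' rep <- bp_report(sim$graph, bp_fix_all(sim$graph)$graph)
#' rep
bp_report <- function(before, after) {
  stopifnot(inherits(before, "biopax_graph"),
            inherits(after, "biopax_graph"))
  census <- bp_census(before)
  n_total <- sum(census$n)
  n_invalid <- census$n[census$category == "INVALID_RECURSIVE"]
  red_b <- bp_redundancy(before)
  red_a <- bp_redundancy(after)
  structure(
    list(
      n_total = n_total,
      n_invalid = n_invalid,
      pct_invalid = if (n_total > 0) 100 * n_invalid / n_total else NA_real_,
      census = census,
      stats_before = bp_component_stats(before),
      stats_after = bp_component_stats(after),
      depth_before = bp_depth_histogram(before),
      depth_after = bp_depth_histogram(after),
      redundancy_before = red_b,
      redundancy_after = red_a
    ),
    class = "bp_report"
  )
}

#' @method glance bp_report
#' @export
glance.bp_report <- function(x, ...) {
  tibble::tibble(
    n_complexes = x$n_total,
    n_invalid = x$n_invalid,
    pct_invalid = x$pct_invalid,
    mean_components_before = x$stats_before$mean,
    sd_components_before = x$stats_before$sd,
    max_components_before = x$stats_before$max,
    mean_components_after = x$stats_after$mean,
    sd_components_after = x$stats_after$sd,
    max_components_after = x$stats_after$max,
    max_depth_before = max(x$depth_before$depth),
    max_depth_after = max(x$depth_after$depth),
    pairs_before = x$redundancy_before$n_pairs,
    cliques_before = x$redundancy_before$n_groups,
    excess_before = x$redundancy_before$n_excess,
    pairs_after = x$redundancy_after$n_pairs,
    cliques_after = x$redundancy_after$n_groups,
    excess_after = x$redundancy_after$n_excess
  )
}

#' @method tidy bp_report
#' @export
tidy.bp_report <- function(x, ...) {
  g <- glance(x)
  tibble::tibble(
    metric = c("mean direct components", "sd direct components",
               "max direct components", "max composition depth",
               "redundant pairs", "redundancy cliques",
               "complexes in excess"),
    before = c(g$mean_components_before, g$sd_components_before,
               g$max_components_before, g$max_depth_before,
               g$pairs_before, g$cliques_before, g$excess_before),
    after = c(g$mean_components_after, g$sd_components_after,
              g$max_components_after, g$max_depth_after,
              g$pairs_after, g$cliques_after, g$excess_after)
  )
}

#' @export
print.bp_report <- function(x, ...) {
  cat("<bp_report>\n")
  cat(sprintf("  complexes: %d, invalid: %d (%d%%)\n",
              x$n_total, x$n_invalid, round(x$pct_invalid)))
  cat(sprintf("  direct components: %.1f (SD %.1f) max %d  ->  %.1f (SD %.1f) max %d\n",
              x$stats_before$mean, x$stats_before$sd, x$stats_before$max,
              x$stats_after$mean, x$stats_after$sd, x$stats_after$max))
  cat(sprintf("  redundancy: %d pairs (%d cliques)  ->  %d pairs (%d cliques)\n",
              x$redundancy_before$n_pairs, x$redundancy_before$n_groups,
              x$redundancy_after$n_pairs, x$redundancy_after$n_groups))
  invisible(x)
}

#' @rdname autoplot-complexfix
#' @method autoplot bp_report
#' @export
autoplot.bp_report <- function(object, ...) {
  hist <- dplyr::bind_rows(
    dplyr::mutate(object$depth_before, when = "before fixing"),
    dplyr::mutate(object$depth_after, when = "after fixing")
  ) |>
    dplyr::mutate(when = factor(.data$when,
                                levels = c("before fixing", "after fixing")))
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$depth), y = .data$n)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::facet_wrap(ggplot2::vars(.data$when)) +
    ggplot2::labs(x = "composition depth", y = "complexes") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
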