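#' Read a BioPAX Level 3 file
#'
#' Parses a BioPAX Level 3 export in RDF/XML (`.owl`) or Turtle (`.ttl`) and
#' builds a `biopax_graph`: a set of tidy tables describing physical
#' entities, complexes with their direct components and stoichiometric
#' coefficients, and interactions, plus the full set of remaining RDF
#' statements carried opaquely so that files round-trip.
#'
#' Component edges lacking a `componentStoichiometry` statement receive a
#' coefficient of 1 and are flagged (`explicit = FALSE`) so the assumption
#' stays auditable downstream.
#'
#' @param path Path to a BioPAX Level 3 file.
#' @param format `"auto"` (default, from extension/content), `"rdfxml"` or
#'   `"turtle"`.
#' @return A `biopax_graph` object; see [bp_graph()] for its tables.
#' @seealso [write_biopax()], [bp_graph()]
#' @export
#' @examples
#' g <- bp_simulate(fixture_config(seed = 1))$graph
#' f <- tempfile(fileext = ".ttl")
#' write_biopax(g, f)
#' g2 <- read_biopax(f)
#' bp_graph_equal(g, g2)
read_biopax <- function(path, format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (format == "auto") format <- sniff_format(path)
  triples <- switch(format,
    rdfxml = read_rdfxml(path),
    turtle = read_turtle(path)
  )
  g <- triples_to_graph(triples)
  g$source_format <- format
  g
}

sniff_format <- function(path) {
  ext <- tolower(sub("^.*\\.", "", path))
  if (ext == "ttl") return("turtle")
  if (ext %in% c("owl", "xml", "rdf")) return("rdfxml")
  head <- paste(readLines(path, n = 5, warn = FALSE), collapse = " ")
  if (grepl("<\\?xml|<rdf:RDF", head)) "rdfxml" else "turtle"
}

#' Write a BioPAX graph to disk
#'
#' Serializes a `biopax_graph` back to RDF/XML or Turtle. Statements about
#' entities the package did not touch are written back verbatim; complex
#' composition (`component` edges and `Stoichiometry` nodes) is regenerated
#' from the graph's component table. Stoichiometry nodes read from the
#' source keep their identifiers; edges created by fixing are given fresh
#' ones; defaulted coefficients (never present in the source) are not
#' materialized, so untouched files round-trip statement-for-statement.
#'
#' @param graph A `biopax_graph`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"rdfxml"` or `"turtle"`.
#' @return `path`, invisibly.
#' @export
write_biopax <- function(graph, path, format = c("auto", "rdfxml", "turtle")) {
  stopifnot(inherits(graph, "biopax_graph"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- if (ext == "ttl") "turtle" else "rdfxml"
  }
  triples <- graph_to_triples(graph)
  switch(format,
    rdfxml = write_rdfxml(triples, path),
    turtle = write_turtle(triples, path)
  )
  invisible(path)
}

entity_kind_of <- function(type_iris) {
  locals <- sub(NS_BP3, "", type_iris[startsWith(type_iris, NS_BP3)],
                fixed = TRUE)
  kinds <- unname(BP_ENTITY_KINDS[locals])
  kinds <- kinds[!is.na(kinds)]
  if (!length(kinds)) return(NA_character_)
  # most specific wins; 'complex' first so Complex-typed nodes are complexes
  priority <- c("complex", "protein", "small-molecule", "dna", "rna",
                "other-physical-entity")
  priority[min(match(kinds, priority))]
}

## Build the domain view from a triple table. The component/stoichiometry
## statements of complexes are consumed; everything else stays residual.
triples_to_graph <- function(triples) {
  has_bp3 <- any(startsWith(triples$predicate, NS_BP3)) ||
    any(triples$predicate == RDF_TYPE & startsWith(triples$object, NS_BP3))
  if (!has_bp3) {
    hint <- if (any(startsWith(triples$predicate, NS_BP2)) ||
                any(triples$object[triples$predicate == RDF_TYPE] |>
                      startsWith(NS_BP2))) {
      " (the file uses BioPAX Level 2 vocabulary)"
    } else ""
    stop("not a BioPAX Level 3 document: no Level 3 vocabulary found", hint,
         call. = FALSE)
  }

  types <- triples[triples$predicate == RDF_TYPE & triples$obj_type == "iri", ]
  kind_tbl <- types |>
    dplyr::group_by(iri = .data$subject) |>
    dplyr::summarise(kind = entity_kind_of(.data$object), .groups = "drop") |>
    dplyr::filter(!is.na(.data$kind))

  names_tbl <- triples |>
    dplyr::filter(.data$predicate == bp3("displayName"),
                  .data$obj_type == "literal") |>
    dplyr::distinct(.data$subject, .keep_all = TRUE) |>
    dplyr::transmute(iri = .data$subject, display_name = .data$object)

  entities <- kind_tbl |>
    dplyr::left_join(names_tbl, by = "iri") |>
    dplyr::arrange(.data$iri)

  complex_iris <- entities$iri[entities$kind == "complex"]

  loc_tbl <- triples |>
    dplyr::filter(.data$predicate == bp3("cellularLocation"),
                  .data$subject %in% complex_iris) |>
    dplyr::distinct(.data$subject, .keep_all = TRUE) |>
    dplyr::transmute(iri = .data$subject, cellular_location = .data$object)

  complexes <- tibble::tibble(iri = complex_iris) |>
    dplyr::left_join(loc_tbl, by = "iri") |>
    dplyr::arrange(.data$iri)
  if (!"cellular_location" %in% names(complexes)) {
    complexes$cellular_location <- character(0)
  }

  comp_triples <- triples |>
    dplyr::filter(.data$predicate == bp3("component"),
                  .data$subject %in% complex_iris)
  missing_refs <- setdiff(comp_triples$object, entities$iri)
  if (length(missing_refs)) {
    stop("referential-integrity error: component edges point to undeclared ",
         "physical entities: ", paste(missing_refs, collapse = ", "),
         call. = FALSE)
  }

  ## componentStoichiometry links and the Stoichiometry nodes they reference
  st_links <- triples |>
    dplyr::filter(.data$predicate == bp3("componentStoichiometry"),
                  .data$subject %in% complex_iris) |>
    dplyr::select(complex_iri = "subject", stoich_iri = "object")
  st_pe <- triples |>
    dplyr::filter(.data$predicate == bp3("physicalEntity")) |>
    dplyr::select(stoich_iri = "subject", component_iri = "object")
  st_coef <- triples |>
    dplyr::filter(.data$predicate == bp3("stoichiometricCoefficient"),
                  .data$obj_type == "literal") |>
    dplyr::select(stoich_iri = "subject", coef_chr = "object")
  stoich <- st_links |>
    dplyr::inner_join(st_pe, by = "stoich_iri") |>
    dplyr::inner_join(st_coef, by = "stoich_iri") |>
    dplyr::mutate(coefficient = as.numeric(.data$coef_chr)) |>
    dplyr::select(-"coef_chr")
  if (any(!is.finite(stoich$coefficient)) || any(stoich$coefficient <= 0)) {
    bad <- stoich$stoich_iri[!is.finite(stoich$coefficient) |
                               stoich$coefficient <= 0]
    stop("invalid stoichiometric coefficient (must be a positive number) ",
         "at: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- stoich |>
    dplyr::distinct(.data$complex_iri, .data$component_iri,
                    .data$coefficient) |>
    dplyr::count(.data$complex_iri, .data$component_iri) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("conflicting stoichiometry statements for edges: ",
         paste(paste0(dup$complex_iri, " -> ", dup$component_iri),
               collapse = ", "), call. = FALSE)
  }
  stoich <- stoich |>
    dplyr::distinct(.data$complex_iri, .data$component_iri,
                    .keep_all = TRUE)

  components <- comp_triples |>
    dplyr::distinct(complex_iri = .data$subject,
                    component_iri = .data$object) |>
    dplyr::left_join(stoich, by = c("complex_iri", "component_iri")) |>
    dplyr::mutate(
      explicit = !is.na(.data$coefficient),
      coefficient = dplyr::coalesce(.data$coefficient, 1)
    ) |>
    dplyr::select("complex_iri", "component_iri", "coefficient",
                  "explicit", "stoich_iri") |>
    dplyr::arrange(.data$complex_iri, .data$component_iri)

  ## interactions: union over the participation properties, one hop
  interaction_types <- paste0(NS_BP3, BP_INTERACTION_CLASSES)
  interaction_iris <- unique(types$subject[types$object %in%
                                             interaction_types])
  part_preds <- paste0(NS_BP3, BP_PARTICIPATION_PROPS)
  interactions <- triples |>
    dplyr::filter(.data$subject %in% interaction_iris,
                  .data$predicate %in% part_preds,
                  .data$obj_type != "literal",
                  .data$object %in% entities$iri) |>
    dplyr::distinct(interaction_iri = .data$subject,
                    property = sub(NS_BP3, "", .data$predicate, fixed = TRUE),
                    participant_iri = .data$object) |>
    dplyr::arrange(.data$interaction_iri, .data$participant_iri)
  ## interactions with no resolvable participants still count as interactions
  all_interactions <- tibble::tibble(iri = sort(interaction_iris))

  consumed_st <- stats::na.omit(unique(components$stoich_iri))
  residual <- triples |>
    dplyr::anti_join(comp_triples,
                     by = c("subject", "predicate", "object")) |>
    dplyr::filter(!(.data$predicate == bp3("componentStoichiometry") &
                      .data$object %in% consumed_st),
                  !.data$subject %in% consumed_st)

  structure(
    list(
      entities = entities,
      complexes = complexes,
      components = components,
      interactions = interactions,
      interaction_iris = all_interactions,
      residual = sort_triples(residual),
      source_format = NA_character_
    ),
    class = "biopax_graph"
  )
}

graph_to_triples <- function(graph) {
  comp <- graph$components
  rows <- list(graph$residual)
  if (nrow(comp)) {
    comp <- dplyr::arrange(comp, .data$complex_iri, .data$component_iri)
    rows[[length(rows) + 1L]] <- triple(
      comp$complex_iri, bp3("component"), comp$component_iri)
    needs_node <- comp$explicit
    st <- comp[needs_node, , drop = FALSE]
    if (nrow(st)) {
      existing <- unique(c(graph$residual$subject, graph$residual$object))
      minted <- st |>
        dplyr::group_by(.data$complex_iri) |>
        dplyr::mutate(.k = dplyr::row_number()) |>
        dplyr::ungroup()
      iri <- minted$stoich_iri
      fresh <- paste0(minted$complex_iri, "_cfx_stoich_", minted$.k)
      clash <- is.na(iri) & fresh %in% existing
      fresh[clash] <- paste0(fresh[clash], "_x")
      iri[is.na(iri)] <- fresh[is.na(iri)]
      rows[[length(rows) + 1L]] <- triple(
        minted$complex_iri, bp3("componentStoichiometry"), iri)
      rows[[length(rows) + 1L]] <- triple(iri, RDF_TYPE, bp3("Stoichiometry"))
      rows[[length(rows) + 1L]] <- triple(
        iri, bp3("physicalEntity"), minted$component_iri)
      rows[[length(rows) + 1L]] <- literal_triple(
        iri, bp3("stoichiometricCoefficient"),
        format_coefficient(minted$coefficient),
        datatype = paste0(NS_XSD, "float"))
    }
  }
  sort_triples(dplyr::distinct(dplyr::bind_rows(rows)))
}

#' Construct a BioPAX graph from tidy tables
#'
#' Builds a `biopax_graph` programmatically, the same object [read_biopax()]
#' produces, by synthesizing the corresponding BioPAX Level 3 statements.
#' Used by the fixture generator and handy in tests.
#'
#' @param entities Tibble with columns `iri`, `kind` (one of `protein`,
#'   `small-molecule`, `dna`, `rna`, `complex`, `other-physical-entity`) and
#'   optionally `display_name`.
#' @param components Tibble with columns `complex_iri`, `component_iri`,
#'   `coefficient` and optionally `explicit` (default `TRUE`; `FALSE` means
#'   the coefficient is a defaulted 1 that will not be serialized).
#' @param locations Tibble with columns `complex_iri`, `location_iri`
#'   assigning cellular-location vocabulary terms to complexes.
#' @param interactions Tibble with columns `interaction_iri`,
#'   `participant_iri` and optionally `property` (default `"participant"`).
#' @return A `biopax_graph` with tables `entities`, `complexes` (with
#'   `cellular_location`), `components` (with per-edge coefficients and the
#'   `explicit` flag), `interactions`, and the opaque `residual` statements.
#' @export
bp_graph <- function(entities, components = NULL, locations = NULL,
                     interactions = NULL) {
  entities <- tibble::as_tibble(entities)
  stopifnot(all(c("iri", "kind") %in% names(entities)))
  if (anyDuplicated(entities$iri)) {
    stop("entity IRIs must be unique", call. = FALSE)
  }
  kind_class <- c(
    "protein" = "Protein", "small-molecule" = "SmallMolecule",
    "dna" = "Dna", "rna" = "Rna", "complex" = "Complex",
    "other-physical-entity" = "PhysicalEntity"
  )
  if (!all(entities$kind %in% names(kind_class))) {
    stop("unknown entity kind(s): ",
         paste(setdiff(entities$kind, names(kind_class)), collapse = ", "),
         call. = FALSE)
  }
  rows <- list(
    triple(entities$iri, RDF_TYPE, bp3(unname(kind_class[entities$kind])))
  )
  if ("display_name" %in% names(entities)) {
    named <- entities[!is.na(entities$display_name), ]
    if (nrow(named)) {
      rows[[length(rows) + 1L]] <- literal_triple(
        named$iri, bp3("displayName"), named$display_name)
    }
  }
  if (!is.null(components) && nrow(components)) {
    components <- tibble::as_tibble(components)
    if (!"explicit" %in% names(components)) components$explicit <- TRUE
    components <- dplyr::arrange(components, .data$complex_iri,
                                 .data$component_iri)
    rows[[length(rows) + 1L]] <- triple(
      components$complex_iri, bp3("component"), components$component_iri)
    expl <- components[components$explicit, , drop = FALSE]
    if (nrow(expl)) {
      st_iri <- paste0(expl$complex_iri, "_stoich_",
                       ave(seq_len(nrow(expl)), expl$complex_iri,
                           FUN = seq_along))
      rows[[length(rows) + 1L]] <- triple(
        expl$complex_iri, bp3("componentStoichiometry"), st_iri)
      rows[[length(rows) + 1L]] <- triple(st_iri, RDF_TYPE,
                                          bp3("Stoichiometry"))
      rows[[length(rows) + 1L]] <- triple(st_iri, bp3("physicalEntity"),
                                          expl$component_iri)
      rows[[length(rows) + 1L]] <- literal_triple(
        st_iri, bp3("stoichiometricCoefficient"),
        format_coefficient(expl$coefficient),
        datatype = paste0(NS_XSD, "float"))
    }
  }
  if (!is.null(locations) && nrow(locations)) {
    locations <- tibble::as_tibble(locations)
    rows[[length(rows) + 1L]] <- triple(
      locations$complex_iri, bp3("cellularLocation"), locations$location_iri)
    locs <- unique(locations$location_iri)
    rows[[length(rows) + 1L]] <- triple(
      locs, RDF_TYPE, bp3("CellularLocationVocabulary"))
    rows[[length(rows) + 1L]] <- literal_triple(
      locs, bp3("term"), sub("^.*[#/]", "", locs))
  }
  if (!is.null(interactions) && nrow(interactions)) {
    interactions <- tibble::as_tibble(interactions)
    if (!"property" %in% names(interactions)) {
      interactions$property <- "participant"
    }
    stopifnot(all(interactions$property %in% BP_PARTICIPATION_PROPS))
    rows[[length(rows) + 1L]] <- triple(
      unique(interactions$interaction_iri), RDF_TYPE, bp3("Interaction"))
    rows[[length(rows) + 1L]] <- triple(
      interactions$interaction_iri, bp3(interactions$property),
      interactions$participant_iri)
  }
  triples_to_graph(dplyr::distinct(dplyr::bind_rows(rows)))
}

#' Compare two BioPAX graphs for equality
#'
#' Identifier-preserving comparison: same entities and kinds, same complex
#' locations, same component edges with identical coefficients and
#' `explicit` flags, and identical residual statement sets (order-blind).
#'
#' @param a,b `biopax_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
bp_graph_equal <- function(a, b) {
  norm_comp <- function(g) {
    g$components |>
      dplyr::select("complex_iri", "component_iri", "coefficient",
                    "explicit") |>
      dplyr::arrange(.data$complex_iri, .data$component_iri)
  }
  norm_res <- function(g) {
    sort_triples(g$residual) |>
      dplyr::select("subject", "predicate", "object", "obj_type",
                    "datatype", "lang")
  }
  isTRUE(all.equal(as.data.frame(dplyr::arrange(a$entities, .data$iri)),
                   as.data.frame(dplyr::arrange(b$entities, .data$iri)))) &&
    isTRUE(all.equal(as.data.frame(dplyr::arrange(a$complexes, .data$iri)),
                     as.data.frame(dplyr::arrange(b$complexes, .data$iri)))) &&
    isTRUE(all.equal(as.data.frame(norm_comp(a)),
                     as.data.frame(norm_comp(b)))) &&
    isTRUE(all.equal(as.data.frame(norm_res(a)),
                     as.data.frame(norm_res(b))))
}

#' @export
print.biopax_graph <- function(x, ...) {
  n_cx <- nrow(x$complexes)
  cat("<biopax_graph>\n")
  cat("  entities:    ", nrow(x$entities), "\n", sep = "")
  cat("  complexes:   ", n_cx, " (",
      sum(!x$complexes$iri %in% x$components$complex_iri),
      " black-box)\n", sep = "")
  cat("  component edges: ", nrow(x$components), " (",
      sum(!x$components$explicit), " with defaulted stoichiometry)\n",
      sep = "")
  cat("  interactions:", nrow(x$interaction_iris), "\n")
  cat("  residual statements:", nrow(x$residual), "\n")
  invisible(x)
}
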