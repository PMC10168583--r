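## RDF/XML reader/writer covering the subset used by BioPAX Level 3 exports:
## node elements (typed or rdf:Description) with rdf:about / rdf:ID /
## rdf:nodeID subjects, property elements holding rdf:resource references,
## nested node elements, or literals with optional rdf:datatype / xml:lang.

expand_qname <- function(qname, nsmap) {
  if (grepl(":", qname, fixed = TRUE)) {
    parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
    prefix <- parts[[1]]
    local <- paste(parts[-1], collapse = ":")
    if (!prefix %in% names(nsmap)) return(NA_character_)
    uri <- nsmap[[prefix]]
    if (is.null(uri) || is.na(uri)) return(NA_character_)
    paste0(uri, local)
  } else {
    NA_character_
  }
}

## attribute lookup by expanded name; attrs is a named vector whose names are
## qualified with the document's prefixes
rdfxml_attr <- function(attrs, nsmap, ns, local) {
  if (length(attrs) == 0) return(NA_character_)
  want <- paste0(ns, local)
  for (nm in names(attrs)) {
    expanded <- expand_qname(nm, nsmap)
    if (!is.na(expanded) && identical(expanded, want)) return(attrs[[nm]])
    # xml2 strips namespace prefixes from attribute names when unambiguous
    if (nm %in% c(local, paste0("xml:", local))) return(attrs[[nm]])
  }
  NA_character_
}

resolve_iri <- function(ref, base) {
  if (is.na(ref)) return(NA_character_)
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", ref)) return(ref)  # absolute
  if (is.na(base) || !nzchar(base)) return(ref)
  base <- sub("#$", "", base)
  if (startsWith(ref, "#")) return(paste0(base, ref))
  if (!nzchar(ref)) return(base)
  paste0(base, "/", ref)
}

read_rdfxml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("RDF/XML parse failure in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  nsmap <- xml2::xml_ns(doc)
  root <- xml2::xml_root(doc)
  root_name <- expand_qname(xml2::xml_name(root, nsmap), nsmap)
  if (!identical(root_name, paste0(NS_RDF, "RDF"))) {
    stop("RDF/XML parse failure in '", path,
         "': document element is not rdf:RDF", call. = FALSE)
  }
  base <- rdfxml_attr(xml2::xml_attrs(root),
                      nsmap, "http://www.w3.org/XML/1998/namespace", "base")

  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 0L)
  acc$blank_counter <- 0L

  push <- function(...) acc$rows[[length(acc$rows) + 1L]] <- triple(...)

  parse_node <- function(el) {
    attrs <- xml2::xml_attrs(el)
    about <- rdfxml_attr(attrs, nsmap, NS_RDF, "about")
    id <- rdfxml_attr(attrs, nsmap, NS_RDF, "ID")
    node_id <- rdfxml_attr(attrs, nsmap, NS_RDF, "nodeID")
    subject <- if (!is.na(about)) {
      resolve_iri(about, base)
    } else if (!is.na(id)) {
      paste0(sub("#$", "", ifelse(is.na(base), "", base)), "#", id)
    } else if (!is.na(node_id)) {
      paste0("_:", node_id)
    } else {
      acc$blank_counter <- acc$blank_counter + 1L
      paste0("_:genid", acc$blank_counter)
    }
    el_name <- expand_qname(xml2::xml_name(el, nsmap), nsmap)
    if (is.na(el_name)) {
      stop("RDF/XML parse failure: unnamespaced node element '",
           xml2::xml_name(el), "'", call. = FALSE)
    }
    if (!identical(el_name, paste0(NS_RDF, "Description"))) {
      push(subject, RDF_TYPE, el_name)
    }
    for (prop in xml2::xml_children(el)) {
      pred <- expand_qname(xml2::xml_name(prop, nsmap), nsmap)
      if (is.na(pred)) {
        stop("RDF/XML parse failure: unnamespaced property element '",
             xml2::xml_name(prop), "'", call. = FALSE)
      }
      pattrs <- xml2::xml_attrs(prop)
      res <- rdfxml_attr(pattrs, nsmap, NS_RDF, "resource")
      pnode <- rdfxml_attr(pattrs, nsmap, NS_RDF, "nodeID")
      ptype <- rdfxml_attr(pattrs, nsmap, NS_RDF, "parseType")
      kids <- xml2::xml_children(prop)
      if (!is.na(ptype)) {
        stop("RDF/XML parse failure: rdf:parseType is not supported",
             call. = FALSE)
      }
      if (!is.na(res)) {
        push(subject, pred, resolve_iri(res, base))
      } else if (!is.na(pnode)) {
        push(subject, pred, paste0("_:", pnode), obj_type = "blank")
      } else if (length(kids) > 0) {
        obj <- parse_node(kids[[1]])
        push(subject, pred, obj,
             obj_type = if (startsWith(obj, "_:")) "blank" else "iri")
      } else {
        dt <- rdfxml_attr(pattrs, nsmap, NS_RDF, "datatype")
        lang <- rdfxml_attr(pattrs, nsmap,
                            "http://www.w3.org/XML/1998/namespace", "lang")
        push(subject, pred, xml2::xml_text(prop),
             obj_type = "literal", datatype = dt, lang = lang)
      }
    }
    subject
  }

  for (el in xml2::xml_children(root)) parse_node(el)
  normalize_triples(dplyr::distinct(dplyr::bind_rows(acc$rows,
                                                     empty_triples())))
}

## split an IRI into (namespace, local) at the last '#' or '/'; local must be
## a valid XML NCName for QName serialization
split_iri <- function(iri) {
  m <- regexpr("[#/][^#/]*$", iri)
  if (m < 0) return(c(NA_character_, NA_character_))
  ns <- substr(iri, 1, m)
  local <- substr(iri, m + 1, nchar(iri))
  if (!grepl("^[A-Za-z_][A-Za-z0-9._-]*$", local)) {
    return(c(NA_character_, NA_character_))
  }
  c(ns, local)
}

## prefix table for serialization: well-known namespaces first, then ns1..
build_prefix_map <- function(iris) {
  base <- c(rdf = NS_RDF, bp = NS_BP3, xsd = NS_XSD, owl = NS_OWL,
            cfx = NS_CFX)
  parts <- vapply(unique(iris), function(i) split_iri(i)[[1]], character(1))
  extra <- setdiff(stats::na.omit(parts), base)
  if (length(extra)) {
    names(extra) <- paste0("ns", seq_along(extra))
    base <- c(base, sort(extra))
    names(base) <- c("rdf", "bp", "xsd", "owl", "cfx",
                     paste0("ns", seq_along(extra)))
  }
  base
}

as_qname <- function(iri, prefixes) {
  sp <- split_iri(iri)
  if (is.na(sp[[1]])) return(NA_character_)
  hit <- match(sp[[1]], prefixes)
  if (is.na(hit)) return(NA_character_)
  paste0(names(prefixes)[hit], ":", sp[[2]])
}

write_rdfxml <- function(triples, path) {
  triples <- sort_triples(triples)
  qname_iris <- unique(c(
    triples$predicate,
    triples$object[triples$predicate == RDF_TYPE & triples$obj_type == "iri"]
  ))
  prefixes <- build_prefix_map(qname_iris)
  ns_attrs <- stats::setNames(unname(prefixes),
                              paste0("xmlns:", names(prefixes)))
  doc <- do.call(xml2::xml_new_root, c(list("rdf:RDF"), as.list(ns_attrs)))

  subjects <- unique(triples$subject)
  for (s in subjects) {
    rows <- triples[triples$subject == s, ]
    is_type <- rows$predicate == RDF_TYPE & rows$obj_type == "iri"
    type_q <- vapply(rows$object[is_type], as_qname, character(1),
                     prefixes = prefixes)
    el_name <- "rdf:Description"
    consumed_type <- NA_character_
    usable <- which(!is.na(type_q))
    if (length(usable) > 0) {
      el_name <- type_q[[usable[[1]]]]
      consumed_type <- rows$object[is_type][usable[[1]]]
    }
    if (startsWith(s, "_:")) {
      node <- xml2::xml_add_child(doc, el_name, "rdf:nodeID" = sub("^_:", "", s))
    } else {
      node <- xml2::xml_add_child(doc, el_name, "rdf:about" = s)
    }
    for (k in seq_len(nrow(rows))) {
      pred <- rows$predicate[[k]]
      obj <- rows$object[[k]]
      if (identical(pred, RDF_TYPE) && identical(obj, consumed_type) &&
          rows$obj_type[[k]] == "iri") {
        consumed_type <- NA_character_  # drop exactly one copy
        next
      }
      pq <- as_qname(pred, prefixes)
      if (is.na(pq)) {
        stop("cannot serialize predicate '", pred, "' as RDF/XML QName",
             call. = FALSE)
      }
      ot <- rows$obj_type[[k]]
      if (ot == "iri") {
        xml2::xml_add_child(node, pq, "rdf:resource" = obj)
      } else if (ot == "blank") {
        xml2::xml_add_child(node, pq, "rdf:nodeID" = sub("^_:", "", obj))
      } else {
        lit <- xml2::xml_add_child(node, pq)
        xml2::xml_text(lit) <- obj
        dt <- rows$datatype[[k]]
        if (!is.na(dt)) xml2::xml_set_attr(lit, "rdf:datatype", dt)
        lg <- rows$lang[[k]]
        if (!is.na(lg)) xml2::xml_set_attr(lit, "xml:lang", lg)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
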