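## Turtle reader/writer for the BioPAX subset: prefix declarations, IRI and
## prefixed-name terms, blank node labels, typed/langtagged literals, the
## 'a' keyword and ';'/',' predicate-object lists. Collections and anonymous
## bracketed nodes are rejected explicitly.

TTL_TOKEN_RE <- paste0(
  '"""(?:[^"\\\\]|\\\\.|"(?!""))*"""',                 # long string
  '|"(?:[^"\\\\\n]|\\\\.)*"',                          # string
  "|<[^<>\"{}|^`\\\\[:space:]]*>",                     # IRIREF
  "|@[A-Za-z][A-Za-z0-9-]*",                           # @prefix/@base/langtag
  "|\\^\\^",
  "|_:[A-Za-z0-9_][A-Za-z0-9_.-]*",                    # blank node label
  "|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_%][A-Za-z0-9_.%-]*", # prefixed name
  "|[A-Za-z_][A-Za-z0-9_.-]*:",                        # prefix-only name
  "|[+-]?[0-9]+\\.[0-9]+(?:[eE][+-]?[0-9]+)?",         # decimal/double
  "|[+-]?[0-9]+",                                      # integer
  "|#[^\n]*",                                          # comment
  "|[;,.()\\[\\]]",
  "|\\b(?:a|PREFIX|BASE|true|false)\\b"
)

ttl_unescape <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  out <- character(0)
  i <- 1L
  n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "\\" && i < n) {
      nxt <- substr(x, i + 1L, i + 1L)
      if (nxt == "u") {
        code <- strtoi(substr(x, i + 2L, i + 5L), 16L)
        out <- c(out, intToUtf8(code)); i <- i + 6L
      } else if (nxt == "U") {
        code <- strtoi(substr(x, i + 2L, i + 9L), 16L)
        out <- c(out, intToUtf8(code)); i <- i + 10L
      } else {
        out <- c(out, switch(nxt,
          "n" = "\n", "t" = "\t", "r" = "\r", "b" = "\b", "f" = "\f",
          '"' = '"', "'" = "'", "\\" = "\\",
          stop("Turtle parse failure: bad escape '\\", nxt, "'",
               call. = FALSE)))
        i <- i + 2L
      }
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste0(out, collapse = "")
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ttl_tokenize <- function(text, path) {
  m <- gregexpr(TTL_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[[1]] == -1) m <- integer(0)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # verify full coverage: anything between tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (k in seq_along(starts)) {
    covered[seq.int(starts[[k]], length.out = lens[[k]])] <- TRUE
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(bad)) {
    pos <- bad[[1]]
    line <- sum(chars[seq_len(pos)] == "\n") + 1L
    stop("Turtle parse failure in '", path, "' at line ", line,
         ": unexpected character '", chars[[pos]], "'", call. = FALSE)
    }
  toks <- substring(text, starts, starts + lens - 1L)
  toks[!startsWith(toks, "#")]
}

read_turtle <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  toks <- ttl_tokenize(text, path)
  prefixes <- character(0)
  base <- NA_character_
  rows <- list()
  i <- 1L
  n <- length(toks)

  peek <- function() if (i <= n) toks[[i]] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) stop("Turtle parse failure in '", path,
                       "': unexpected end of input", call. = FALSE)
    i <<- i + 1L
    t
  }
  expect <- function(what) {
    t <- advance()
    if (!identical(t, what)) {
      stop("Turtle parse failure in '", path, "': expected '", what,
           "' near token ", i - 1L, " ('", t, "')", call. = FALSE)
    }
  }
  term_iri <- function(tok) {
    if (startsWith(tok, "<")) {
      ref <- ttl_unescape(substr(tok, 2L, nchar(tok) - 1L))
      return(resolve_iri(ref, base))
    }
    if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*:", tok)) {
      colon <- regexpr(":", tok, fixed = TRUE)
      prefix <- substr(tok, 1L, colon - 1L)
      local <- substr(tok, colon + 1L, nchar(tok))
      uri <- if (prefix %in% names(prefixes)) prefixes[[prefix]] else NULL
      if (is.null(uri)) {
        stop("Turtle parse failure in '", path, "': undeclared prefix '",
             prefix, ":'", call. = FALSE)
      }
      return(paste0(uri, local))
    }
    stop("Turtle parse failure in '", path, "': expected IRI, got '", tok,
         "'", call. = FALSE)
  }

  parse_object <- function() {
    tok <- advance()
    if (tok %in% c("(", "[")) {
      stop("Turtle parse failure in '", path,
           "': collections/anonymous nodes are not supported", call. = FALSE)
    }
    if (startsWith(tok, "_:")) {
      return(list(object = tok, obj_type = "blank",
                  datatype = NA_character_, lang = NA_character_))
    }
    if (startsWith(tok, '"')) {
      raw <- if (startsWith(tok, '"""')) {
        substr(tok, 4L, nchar(tok) - 3L)
      } else {
        substr(tok, 2L, nchar(tok) - 1L)
      }
      val <- ttl_unescape(raw)
      dt <- NA_character_
      lang <- NA_character_
      if (identical(peek(), "^^")) {
        advance()
        dt <- term_iri(advance())
      } else if (!is.na(peek()) && grepl("^@[A-Za-z]", peek()) &&
                 !peek() %in% c("@prefix", "@base")) {
        lang <- sub("^@", "", advance())
      }
      return(list(object = val, obj_type = "literal", datatype = dt,
                  lang = lang))
    }
    if (grepl("^[+-]?[0-9]", tok)) {
      dt <- if (grepl("[.eE]", tok)) paste0(NS_XSD, "decimal")
            else paste0(NS_XSD, "integer")
      return(list(object = tok, obj_type = "literal", datatype = dt,
                  lang = NA_character_))
    }
    if (tok %in% c("true", "false")) {
      return(list(object = tok, obj_type = "literal",
                  datatype = paste0(NS_XSD, "boolean"), lang = NA_character_))
    }
    list(object = term_iri(tok), obj_type = "iri",
         datatype = NA_character_, lang = NA_character_)
  }

  while (i <= n) {
    tok <- peek()
    if (tok %in% c("@prefix", "PREFIX")) {
      advance()
      ptok <- advance()
      if (!grepl(":$", ptok) && !grepl("^[A-Za-z_].*:", ptok)) {
        stop("Turtle parse failure in '", path, "': bad prefix declaration",
             call. = FALSE)
      }
      pname <- sub(":.*$", "", ptok)
      iritok <- advance()
      prefixes[[pname]] <- ttl_unescape(substr(iritok, 2L,
                                               nchar(iritok) - 1L))
      if (identical(tok, "@prefix")) expect(".")
      next
    }
    if (tok %in% c("@base", "BASE")) {
      advance()
      iritok <- advance()
      base <- ttl_unescape(substr(iritok, 2L, nchar(iritok) - 1L))
      if (identical(tok, "@base")) expect(".")
      next
    }
    # triples block
    stok <- advance()
    subject <- if (startsWith(stok, "_:")) stok else term_iri(stok)
    repeat {
      ptok <- advance()
      pred <- if (identical(ptok, "a")) RDF_TYPE else term_iri(ptok)
      repeat {
        o <- parse_object()
        rows[[length(rows) + 1L]] <- triple(
          subject, pred, o$object, o$obj_type, o$datatype, o$lang)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      nxt <- advance()
      if (identical(nxt, ";")) {
        if (identical(peek(), ".")) { advance(); break }  # trailing ';'
        next
      }
      if (identical(nxt, ".")) break
      stop("Turtle parse failure in '", path, "': expected ';' or '.', got '",
           nxt, "'", call. = FALSE)
    }
  }
  normalize_triples(dplyr::distinct(dplyr::bind_rows(rows,
                                                     empty_triples())))
}

ttl_term <- function(iri, prefixes) {
  q <- as_qname(iri, prefixes)
  if (!is.na(q)) q else paste0("<", iri, ">")
}

ttl_object <- function(row, prefixes) {
  if (row$obj_type == "iri") return(ttl_term(row$object, prefixes))
  if (row$obj_type == "blank") return(row$object)
  lit <- paste0('"', ttl_escape(row$object), '"')
  if (!is.na(row$lang)) return(paste0(lit, "@", row$lang))
  if (!is.na(row$datatype) &&
      !identical(row$datatype, paste0(NS_XSD, "string"))) {
    return(paste0(lit, "^^", ttl_term(row$datatype, prefixes)))
  }
  lit
}

write_turtle <- function(triples, path) {
  triples <- sort_triples(triples)
  prefixes <- build_prefix_map(unique(c(
    triples$predicate,
    triples$object[triples$obj_type == "iri"],
    triples$subject[!startsWith(triples$subject, "_:")],
    stats::na.omit(triples$datatype)
  )))
  lines <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  lines <- c(lines, "")
  for (s in unique(triples$subject)) {
    rows <- triples[triples$subject == s, ]
    sterm <- if (startsWith(s, "_:")) s else ttl_term(s, prefixes)
    parts <- character(0)
    for (p in unique(rows$predicate)) {
      prow <- rows[rows$predicate == p, ]
      pterm <- if (identical(p, RDF_TYPE)) "a" else ttl_term(p, prefixes)
      objs <- vapply(seq_len(nrow(prow)),
                     function(k) ttl_object(prow[k, ], prefixes),
                     character(1))
      parts <- c(parts, paste0("    ", pterm, " ",
                               paste(objs, collapse = ", ")))
    }
    lines <- c(lines, paste0(sterm, "\n", paste(parts, collapse = " ;\n"),
                             " ."), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
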