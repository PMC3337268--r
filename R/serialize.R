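# RDF term constructors. A "term" is a tagged list so a triple's object can
# be an IRI, a typed literal, or an inline collection of IRIs (used for
# owl:unionOf). No R RDF stack is available, and deterministic byte-stable
# serialization is a design requirement here, so the writers and the
# canonical-subset Turtle reader are implemented in-package.
t_iri <- function(x) list(kind = "iri", value = x)
t_lit <- function(x, dtype = NA_character_) {
  list(kind = "lit", value = as.character(x), dtype = dtype)
}
t_coll <- function(x) list(kind = "coll", value = x)

.base_prefixes <- function(base_iri) {
  c(":" = paste0(base_iri, "#"), "owl:" = NS_OWL, "rdf:" = NS_RDF,
    "rdfs:" = NS_RDFS, "xsd:" = NS_XSD)
}

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- character(0)
    j <- 1L
    while (j <= nchar(s)) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < nchar(s)) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- c(res, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(res, collapse = "")
  }
  out
}

compress_iri <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_-]*$", local)) {
        return(paste0(p, local))
      }
    }
  }
  paste0("<", iri, ">")
}

term_turtle <- function(o, prefixes) {
  if (o$kind == "iri") return(compress_iri(o$value, prefixes))
  if (o$kind == "coll") {
    return(paste0("( ",
                  paste(vapply(o$value, compress_iri, character(1),
                               prefixes = prefixes), collapse = " "),
                  " )"))
  }
  lit <- paste0("\"", escape_lit(o$value), "\"")
  if (!is.na(o$dtype) && o$dtype != paste0(NS_XSD, "string")) {
    lit <- paste0(lit, "^^", compress_iri(o$dtype, prefixes))
  }
  lit
}

term_sort_key <- function(o) {
  switch(o$kind,
         iri = o$value,
         coll = paste(o$value, collapse = " "),
         lit = o$value)
}

# Canonical Turtle writer: subjects sorted by IRI (an optional `first`
# subject, e.g. the ontology header, leads), rdf:type first within a
# subject, remaining predicates sorted by IRI then object.
rdf_write_turtle <- function(triples, prefixes, first = NULL) {
  stopifnot(is.list(triples))
  header <- paste0("@prefix ", names(prefixes), " <", unname(prefixes),
                   "> .")
  subjects <- unique(vapply(triples, function(t) t$s, character(1)))
  subjects <- subjects[order(match(subjects, first, nomatch = 2L),
                             subjects)]
  rdf_type <- paste0(NS_RDF, "type")
  blocks <- character(0)
  for (s in subjects) {
    st <- keep(triples, ~ identical(.x$s, s))
    keys <- vapply(st, function(t) {
      paste0(if (identical(t$p, rdf_type)) "0" else "1", t$p, "",
             term_sort_key(t$o))
    }, character(1))
    st <- st[order(keys)]
    parts <- vapply(st, function(t) {
      pred <- if (identical(t$p, rdf_type)) "a"
              else compress_iri(t$p, prefixes)
      paste0(pred, " ", term_turtle(t$o, prefixes))
    }, character(1))
    blocks <- c(blocks, paste0(compress_iri(s, prefixes), " ",
                               paste(parts, collapse = " ;\n    "), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

escape_xml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Canonical RDF/XML writer over the same triple form and ordering rules.
rdf_write_rdfxml <- function(triples, prefixes, first = NULL) {
  rdf_type <- paste0(NS_RDF, "type")
  qname <- function(iri) {
    for (p in setdiff(names(prefixes), ":")) {
      ns <- prefixes[[p]]
      if (startsWith(iri, ns)) {
        return(paste0(sub(":$", "", p), ":", substring(iri, nchar(ns) + 1L)))
      }
    }
    NULL
  }
  subjects <- unique(vapply(triples, function(t) t$s, character(1)))
  subjects <- subjects[order(match(subjects, first, nomatch = 2L),
                             subjects)]
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<rdf:RDF xmlns:rdf=\"", NS_RDF, "\" xmlns:rdfs=\"",
                    NS_RDFS, "\" xmlns:owl=\"", NS_OWL, "\" xmlns:xsd=\"",
                    NS_XSD, "\">"))
  for (s in subjects) {
    st <- keep(triples, ~ identical(.x$s, s))
    keys <- vapply(st, function(t) {
      paste0(if (identical(t$p, rdf_type)) "0" else "1", t$p, "",
             term_sort_key(t$o))
    }, character(1))
    st <- st[order(keys)]
    # Use the first rdf:type with a known qname as the typed node element.
    node_name <- "rdf:Description"
    type_used <- -1L
    for (i in seq_along(st)) {
      t <- st[[i]]
      if (identical(t$p, rdf_type) && t$o$kind == "iri") {
        qn <- qname(t$o$value)
        if (!is.null(qn)) { node_name <- qn; type_used <- i; break }
      }
    }
    lines <- c(lines, paste0("  <", node_name, " rdf:about=\"",
                             escape_xml(s), "\">"))
    for (i in seq_along(st)) {
      if (i == type_used) next
      t <- st[[i]]
      pq <- if (identical(t$p, rdf_type)) "rdf:type" else qname(t$p)
      if (is.null(pq)) {
        stop_toxowl(paste0("cannot serialize predicate outside declared ",
                           "namespaces: ", t$p), "toxowl_error")
      }
      o <- t$o
      if (o$kind == "iri") {
        lines <- c(lines, paste0("    <", pq, " rdf:resource=\"",
                                 escape_xml(o$value), "\"/>"))
      } else if (o$kind == "coll") {
        lines <- c(lines,
                   paste0("    <", pq, " rdf:parseType=\"Collection\">"),
                   vapply(o$value, function(m) {
                     paste0("      <rdf:Description rdf:about=\"",
                            escape_xml(m), "\"/>")
                   }, character(1)),
                   paste0("    </", pq, ">"))
      } else {
        attr_dt <- if (!is.na(o$dtype) &&
                       o$dtype != paste0(NS_XSD, "string")) {
          paste0(" rdf:datatype=\"", escape_xml(o$dtype), "\"")
        } else ""
        lines <- c(lines, paste0("    <", pq, attr_dt, ">",
                                 escape_xml(o$value), "</", pq, ">"))
      }
    }
    lines <- c(lines, paste0("  </", node_name, ">"))
  }
  paste0(paste(c(lines, "</rdf:RDF>"), collapse = "\n"), "\n")
}

# --- Reading ---------------------------------------------------------------

tokenize_turtle <- function(text) {
  pattern <- paste(
    '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_][A-Za-z0-9_-]*)?',
    '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^<[^>]*>)?',
    "@prefix",
    "<[^>]*>",
    "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_-]*",
    "[A-Za-z][A-Za-z0-9_.-]*:",
    ":[A-Za-z0-9_][A-Za-z0-9_-]*",
    ":",
    "\\ba\\b",
    "[.;,()]",
    sep = "|")
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, gregexpr(pattern, text, perl = TRUE))[[1]]
}

#' Parse RDF text into a triple table
#'
#' Reads the canonical subset this package emits: Turtle/N3 with `@prefix`
#' declarations, `a`, predicate (`;`) and object (`,`) lists, typed string
#' literals and inline collections, or the package's RDF/XML dialect.
#' Collections are expanded to `rdf:first`/`rdf:rest` chains over generated
#' blank nodes (ids `_:c1`, `_:c2`, ... in reading order).
#'
#' @param text RDF document as a single string.
#' @param format `"turtle"`, `"n3"` (an alias: the package's N3 output is
#'   its Turtle subset) or `"rdf-xml"`.
#' @return A tibble with columns `s`, `p`, `o`, `o_is_literal`, `o_dtype`.
#' @export
rdf_triples <- function(text, format = c("turtle", "n3", "rdf-xml")) {
  format <- match.arg(format)
  if (format == "rdf-xml") parse_rdfxml_triples(text)
  else parse_turtle_triples(text)
}

parse_turtle_triples <- function(text) {
  toks <- tokenize_turtle(text)
  prefixes <- list()
  triples <- list()
  bn <- 0L
  emit <- function(s, p, o, lit = FALSE, dtype = NA_character_) {
    triples[[length(triples) + 1L]] <<-
      list(s = s, p = p, o = o, lit = lit, dtype = dtype)
  }
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NA_character_
  take <- function() {
    if (i > length(toks)) {
      stop_toxowl("unexpected end of RDF text", "toxowl_parse_error")
    }
    t <- toks[[i]]; i <<- i + 1L; t
  }
  resolve_iri <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    colon <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1L, colon)
    local <- substring(tok, colon + 1L)
    ns <- prefixes[[pfx]]
    if (is.null(ns)) {
      stop_toxowl(paste0("undeclared prefix in token ", tok),
                  "toxowl_parse_error")
    }
    paste0(ns, local)
  }
  parse_object <- function(s, p) {
    tok <- take()
    if (identical(tok, "(")) {
      members <- character(0)
      while (!identical(peek(), ")")) members <- c(members, resolve_iri(take()))
      take()
      if (length(members) == 0) {
        emit(s, p, paste0(NS_RDF, "nil"))
        return(invisible())
      }
      nodes <- vapply(seq_along(members), function(k) {
        bn <<- bn + 1L; paste0("_:c", bn)
      }, character(1))
      emit(s, p, nodes[[1]])
      for (k in seq_along(members)) {
        emit(nodes[[k]], paste0(NS_RDF, "first"), members[[k]])
        emit(nodes[[k]], paste0(NS_RDF, "rest"),
             if (k < length(members)) nodes[[k + 1L]]
             else paste0(NS_RDF, "nil"))
      }
    } else if (startsWith(tok, "\"")) {
      dtype <- NA_character_
      body <- tok
      # the datatype marker can only follow the closing quote
      close_q <- regexpr('"(\\^\\^|$)', tok, perl = TRUE)
      if (grepl('\\^\\^', substring(tok, close_q))) {
        body <- substr(tok, 1L, close_q)
        dtype <- resolve_iri(substring(tok, close_q + 3L))
      }
      value <- unescape_lit(substr(body, 2L, nchar(body) - 1L))
      emit(s, p, value, lit = TRUE, dtype = dtype)
    } else {
      emit(s, p, resolve_iri(tok))
    }
  }
  while (i <= length(toks)) {
    tok <- take()
    if (identical(tok, "@prefix")) {
      pfx <- take(); iri <- take(); dot <- take()
      if (!identical(dot, ".")) {
        stop_toxowl("malformed @prefix declaration", "toxowl_parse_error")
      }
      prefixes[[pfx]] <- substr(iri, 2L, nchar(iri) - 1L)
      prefixes <- as.list(prefixes)
      next
    }
    s <- resolve_iri(tok)
    repeat {
      ptok <- take()
      p <- if (identical(ptok, "a")) paste0(NS_RDF, "type")
           else resolve_iri(ptok)
      repeat {
        parse_object(s, p)
        if (!identical(peek(), ",")) break
        take()
      }
      sep <- take()
      if (identical(sep, ".")) break
      if (!identical(sep, ";")) {
        stop_toxowl(paste0("unexpected token '", sep, "' in triple block"),
                    "toxowl_parse_error")
      }
      if (identical(peek(), ".")) { take(); break }
    }
  }
  if (length(triples) == 0) {
    return(tibble(s = character(0), p = character(0), o = character(0),
                  o_is_literal = logical(0), o_dtype = character(0)))
  }
  tibble(
    s = map_chr(triples, "s"), p = map_chr(triples, "p"),
    o = map_chr(triples, "o"),
    o_is_literal = map_lgl(triples, "lit"),
    o_dtype = map_chr(triples, "dtype")
  )
}

parse_rdfxml_triples <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    stop_toxowl(paste0("RDF/XML parse error: ", conditionMessage(e)),
                "toxowl_parse_error", parent = e)
  })
  ns_map <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD)
  expand <- function(qn) {
    parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[[1]] %in% names(ns_map)) {
      stop_toxowl(paste0("unsupported RDF/XML element ", qn),
                  "toxowl_parse_error")
    }
    paste0(ns_map[[parts[[1]]]], parts[[2]])
  }
  triples <- list()
  bn <- 0L
  emit <- function(s, p, o, lit = FALSE, dtype = NA_character_) {
    triples[[length(triples) + 1L]] <<-
      list(s = s, p = p, o = o, lit = lit, dtype = dtype)
  }
  for (node in xml2::xml_children(xml2::xml_root(doc))) {
    s <- xml2::xml_attr(node, "about")
    if (is.na(s)) {
      stop_toxowl("RDF/XML subject node without rdf:about",
                  "toxowl_parse_error")
    }
    qn <- xml2::xml_name(node, ns = xml2::xml_ns(doc))
    if (!identical(qn, "rdf:Description")) {
      emit(s, paste0(NS_RDF, "type"), expand(qn))
    }
    for (prop in xml2::xml_children(node)) {
      pqn <- xml2::xml_name(prop, ns = xml2::xml_ns(doc))
      p <- expand(pqn)
      res <- xml2::xml_attr(prop, "resource")
      ptype <- xml2::xml_attr(prop, "parseType")
      if (!is.na(res)) {
        emit(s, p, res)
      } else if (identical(ptype, "Collection")) {
        members <- vapply(xml2::xml_children(prop), xml2::xml_attr,
                          character(1), attr = "about")
        if (length(members) == 0) {
          emit(s, p, paste0(NS_RDF, "nil"))
        } else {
          nodes <- vapply(seq_along(members), function(k) {
            bn <<- bn + 1L; paste0("_:c", bn)
          }, character(1))
          emit(s, p, nodes[[1]])
          for (k in seq_along(members)) {
            emit(nodes[[k]], paste0(NS_RDF, "first"), members[[k]])
            emit(nodes[[k]], paste0(NS_RDF, "rest"),
                 if (k < length(members)) nodes[[k + 1L]]
                 else paste0(NS_RDF, "nil"))
          }
        }
      } else {
        dtype <- xml2::xml_attr(prop, "datatype")
        emit(s, p, xml2::xml_text(prop), lit = TRUE,
             dtype = if (is.na(dtype)) NA_character_ else dtype)
      }
    }
  }
  if (length(triples) == 0) {
    return(tibble(s = character(0), p = character(0), o = character(0),
                  o_is_literal = logical(0), o_dtype = character(0)))
  }
  tibble(
    s = map_chr(triples, "s"), p = map_chr(triples, "p"),
    o = map_chr(triples, "o"),
    o_is_literal = map_lgl(triples, "lit"),
    o_dtype = map_chr(triples, "dtype")
  )
}

# --- Ontology <-> triples --------------------------------------------------

union_label <- function(labels) {
  paste0("UnionOf_", paste(sort(labels), collapse = "_"))
}

ontology_to_triples <- function(model) {
  model <- canonicalize_ontology(model)
  base <- model$base_iri
  iri <- function(label) paste0(base, "#", label)
  tr <- list()
  push <- function(s, p, o) tr[[length(tr) + 1L]] <<- list(s = s, p = p, o = o)

  push(base, paste0(NS_RDF, "type"), t_iri(paste0(NS_OWL, "Ontology")))

  for (i in seq_len(nrow(model$classes))) {
    cl <- model$classes[i, ]
    s <- iri(cl$label)
    push(s, paste0(NS_RDF, "type"), t_iri(paste0(NS_OWL, "Class")))
    push(s, paste0(NS_RDFS, "label"), t_lit(cl$label))
    if (!is.na(cl$comment)) {
      push(s, paste0(NS_RDFS, "comment"), t_lit(cl$comment))
    }
  }
  for (i in seq_len(nrow(model$subclass_axioms))) {
    ax <- model$subclass_axioms[i, ]
    push(iri(ax$child), paste0(NS_RDFS, "subClassOf"), t_iri(iri(ax$parent)))
  }

  unions <- new.env(parent = emptyenv())
  class_set_term <- function(labels) {
    if (length(labels) == 1) return(t_iri(iri(labels)))
    ul <- union_label(labels)
    if (!exists(ul, envir = unions, inherits = FALSE)) {
      assign(ul, labels, envir = unions)
      s <- iri(ul)
      push(s, paste0(NS_RDF, "type"), t_iri(paste0(NS_OWL, "Class")))
      push(s, paste0(NS_OWL, "unionOf"),
           t_coll(vapply(sort(labels), iri, character(1))))
    }
    t_iri(iri(ul))
  }

  for (i in seq_len(nrow(model$object_properties))) {
    p <- model$object_properties[i, ]
    s <- iri(p$label)
    push(s, paste0(NS_RDF, "type"), t_iri(paste0(NS_OWL, "ObjectProperty")))
    push(s, paste0(NS_RDFS, "label"), t_lit(p$label))
    if (!is.na(p$comment)) {
      push(s, paste0(NS_RDFS, "comment"), t_lit(p$comment))
    }
    if (length(p$domain[[1]])) {
      push(s, paste0(NS_RDFS, "domain"), class_set_term(p$domain[[1]]))
    }
    if (length(p$range[[1]])) {
      push(s, paste0(NS_RDFS, "range"), class_set_term(p$range[[1]]))
    }
  }
  for (i in seq_len(nrow(model$datatype_properties))) {
    p <- model$datatype_properties[i, ]
    s <- iri(p$label)
    push(s, paste0(NS_RDF, "type"),
         t_iri(paste0(NS_OWL, "DatatypeProperty")))
    push(s, paste0(NS_RDFS, "label"), t_lit(p$label))
    if (!is.na(p$comment)) {
      push(s, paste0(NS_RDFS, "comment"), t_lit(p$comment))
    }
    if (length(p$domain[[1]])) {
      push(s, paste0(NS_RDFS, "domain"), class_set_term(p$domain[[1]]))
    }
    push(s, paste0(NS_RDFS, "range"), t_iri(.xsd_literal[[p$datatype]]))
  }
  tr
}

#' Serialize an ontology model to OWL
#'
#' Writes Turtle or RDF/XML with a canonical ordering -- subjects sorted by
#' IRI (ontology header first), `rdf:type` leading each block, remaining
#' predicates sorted -- so that identical models always produce identical
#' bytes. A domain or range spanning several classes is written as a named
#' `owl:unionOf` class expression (label `UnionOf_<members>`) with a
#' deterministic member order. The model must pass [check_structure()];
#' otherwise emission refuses and reports the issues.
#'
#' @param model An `ontology_model`.
#' @param format `"turtle"` or `"rdf-xml"`.
#' @return The serialized document as a single string.
#' @examples
#' m <- ontology_model() |>
#'   add_class("Study") |>
#'   add_class("Background") |>
#'   add_object_property("hasBackground", "Study", "Background")
#' cat(emit_owl(m, "turtle"))
#' @export
emit_owl <- function(model, format = c("turtle", "rdf-xml")) {
  format <- match.arg(format)
  issues <- check_structure(model)
  if (nrow(issues) > 0) {
    stop_toxowl(paste0("refusing to serialize a structurally invalid ",
                       "model:\n", paste0("  - [", issues$rule, "] ",
                                          issues$label, ": ", issues$detail,
                                          collapse = "\n")),
                "toxowl_invalid_model", issues = issues)
  }
  tr <- ontology_to_triples(model)
  prefixes <- .base_prefixes(model$base_iri)
  if (format == "turtle") rdf_write_turtle(tr, prefixes, first = model$base_iri)
  else rdf_write_rdfxml(tr, prefixes, first = model$base_iri)
}

local_part <- function(iri) {
  sub("^.*[#/]", "", iri)
}

#' Read an ontology model back from OWL text
#'
#' Inverse of [emit_owl()] on the package's serialization subset: rebuilds
#' the `ontology_model` (classes with comments, object/datatype properties
#' with union domains and ranges expanded, subclass axioms) from Turtle or
#' RDF/XML. Triple order does not matter.
#'
#' @param text Serialized OWL document.
#' @param format `"turtle"` or `"rdf-xml"`.
#' @return An `ontology_model`.
#' @export
parse_owl <- function(text, format = c("turtle", "rdf-xml")) {
  format <- match.arg(format)
  tr <- if (format == "turtle") parse_turtle_triples(text)
        else parse_rdfxml_triples(text)
  assemble_ontology(tr)
}

assemble_ontology <- function(tr) {
  rdf_type <- paste0(NS_RDF, "type")
  obj_of <- function(s, p) tr$o[tr$s == s & tr$p == p & !tr$o_is_literal]
  lit_of <- function(s, p) {
    v <- tr$o[tr$s == s & tr$p == p & tr$o_is_literal]
    if (length(v)) v[[1]] else NA_character_
  }
  typed <- function(type_iri) unique(tr$s[tr$p == rdf_type & tr$o == type_iri])

  onto_subj <- typed(paste0(NS_OWL, "Ontology"))
  base <- if (length(onto_subj)) sub("#$", "", onto_subj[[1]])
          else DEFAULT_BASE_IRI

  # Union class expressions: subject -> member labels (via rdf list chain).
  follow_list <- function(head) {
    out <- character(0)
    nil <- paste0(NS_RDF, "nil")
    while (!identical(head, nil)) {
      out <- c(out, obj_of(head, paste0(NS_RDF, "first")))
      nxt <- obj_of(head, paste0(NS_RDF, "rest"))
      if (length(nxt) == 0) {
        stop_toxowl("broken RDF collection in ontology text",
                    "toxowl_parse_error")
      }
      head <- nxt[[1]]
    }
    out
  }
  union_subjects <- unique(tr$s[tr$p == paste0(NS_OWL, "unionOf")])
  union_members <- lapply(union_subjects, function(s) {
    local_part(follow_list(obj_of(s, paste0(NS_OWL, "unionOf"))[[1]]))
  })
  names(union_members) <- union_subjects

  expand_set <- function(iris) {
    out <- character(0)
    for (x in iris) {
      if (x %in% union_subjects) out <- c(out, union_members[[x]])
      else out <- c(out, local_part(x))
    }
    sort(unique(out))
  }

  m <- ontology_model(base)
  class_subjects <- setdiff(typed(paste0(NS_OWL, "Class")), union_subjects)
  class_subjects <- class_subjects[!startsWith(class_subjects, "_:")]
  for (s in sort(class_subjects)) {
    m <- add_class(m, local_part(s), lit_of(s, paste0(NS_RDFS, "comment")))
  }
  for (s in sort(class_subjects)) {
    for (p in obj_of(s, paste0(NS_RDFS, "subClassOf"))) {
      m <- add_subclass(m, local_part(s), local_part(p))
    }
  }
  for (s in sort(typed(paste0(NS_OWL, "ObjectProperty")))) {
    m <- add_object_property(
      m, local_part(s),
      expand_set(obj_of(s, paste0(NS_RDFS, "domain"))),
      expand_set(obj_of(s, paste0(NS_RDFS, "range"))),
      comment = lit_of(s, paste0(NS_RDFS, "comment")))
  }
  rev_lit <- stats::setNames(names(.xsd_literal), unname(.xsd_literal))
  for (s in sort(typed(paste0(NS_OWL, "DatatypeProperty")))) {
    rng <- obj_of(s, paste0(NS_RDFS, "range"))
    dt <- if (length(rng) && rng[[1]] %in% names(rev_lit)) rev_lit[[rng[[1]]]]
          else "string"
    m <- add_datatype_property(
      m, local_part(s),
      expand_set(obj_of(s, paste0(NS_RDFS, "domain"))),
      datatype = dt,
      comment = lit_of(s, paste0(NS_RDFS, "comment")))
  }
  m
}
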