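XSD_NS <- "http://www.w3.org/2001/XMLSchema"

# XSD builtin simple types supported as leaf kinds.
.xsd_kind_map <- c(
  "xs:string" = "string", "xs:token" = "string",
  "xs:integer" = "integer", "xs:int" = "integer", "xs:long" = "integer",
  "xs:nonNegativeInteger" = "integer", "xs:positiveInteger" = "integer",
  "xs:decimal" = "decimal", "xs:double" = "decimal", "xs:float" = "decimal"
)

local_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

#' Parse an XSD-style schema into a schema graph
#'
#' Reads the supported XSD subset -- `xs:element`, inline or named
#' `xs:complexType` with `xs:sequence`/`xs:choice`, `xs:simpleType` with a
#' string restriction carrying `xs:enumeration` facets, and
#' `minOccurs`/`maxOccurs` -- into a flat table of fields keyed by their
#' slash-joined path from the schema root. Named global types are expanded at
#' every point of use; anonymous inline types take their enclosing element's
#' name; `xs:choice` is treated structurally like `xs:sequence`. Any construct
#' outside this subset (e.g. `xs:any`, `xs:attribute`, element references) is
#' a hard error naming the construct and the path at which it occurred:
#' conversion correctness depends on accounting for every declared field, so
#' nothing is silently skipped.
#'
#' @param x Path to an `.xsd` file, or a single string containing the schema
#'   document itself (anything containing a `<` is treated as literal XML).
#' @return A `schema_graph` object. Its field table (see [schema_fields()])
#'   has one row per declared element with columns `path`, `name`,
#'   `parent_path`, `depth`, `value_kind` (`complex`, `string`, `integer` or
#'   `decimal`), `enumeration` (list column; `NULL` when absent),
#'   `min_occurs` and `max_occurs` (`Inf` for `unbounded`).
#' @examples
#' g <- parse_schema(toxowl_example("toxml-mini.xsd"))
#' schema_fields(g)
#' @seealso [ambiguous_names()], [emit_schema()], [convert_schema()]
#' @export
parse_schema <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  doc <- tryCatch(
    suppressWarnings(
      if (grepl("<", x, fixed = TRUE)) xml2::read_xml(x) else {
        if (!file.exists(x)) stop_toxowl(paste0("no such schema file: ", x),
                                         "toxowl_parse_error")
        xml2::read_xml(x)
      }),
    error = function(e) stop_toxowl(
      paste0("schema parse error: ", conditionMessage(e)),
      "toxowl_parse_error", parent = e)
  )
  root <- xml2::xml_root(doc)
  if (local_name(root) != "schema") {
    stop_toxowl(paste0("expected document root xs:schema, found ",
                       xml2::xml_name(root)), "toxowl_parse_error")
  }

  kids <- xml2::xml_children(root)
  named_types <- list()
  for (k in kids) {
    ln <- local_name(k)
    if (ln %in% c("complexType", "simpleType")) {
      nm <- xml2::xml_attr(k, "name")
      if (is.na(nm)) {
        stop_toxowl(paste0("top-level xs:", ln, " without a name"),
                    "toxowl_parse_error")
      }
      named_types[[nm]] <- k
    } else if (!ln %in% c("element", "annotation")) {
      stop_toxowl(paste0("unsupported construct xs:", ln, " at schema root"),
                  "toxowl_unsupported_construct")
    }
  }

  rows <- new.env(parent = emptyenv())
  rows$tab <- list()
  add_row <- function(...) rows$tab[[length(rows$tab) + 1L]] <- list(...)

  parse_occurs <- function(node) {
    mn <- xml2::xml_attr(node, "minOccurs")
    mx <- xml2::xml_attr(node, "maxOccurs")
    list(
      min = if (is.na(mn)) 1L else as.integer(mn),
      max = if (is.na(mx)) 1 else if (identical(mx, "unbounded")) Inf
            else as.numeric(mx)
    )
  }

  # Collect xs:element nodes beneath a complexType, flattening nested
  # sequence/choice groups; anything else in the subtree is unsupported.
  group_elements <- function(node, path) {
    out <- list()
    for (ch in xml2::xml_children(node)) {
      ln <- local_name(ch)
      if (ln == "element") {
        out[[length(out) + 1L]] <- ch
      } else if (ln %in% c("sequence", "choice")) {
        out <- c(out, group_elements(ch, path))
      } else if (ln != "annotation") {
        stop_toxowl(paste0("unsupported construct xs:", ln, " at path ", path),
                    "toxowl_unsupported_construct")
      }
    }
    out
  }

  parse_simple <- function(node, path) {
    restr <- NULL
    for (ch in xml2::xml_children(node)) {
      ln <- local_name(ch)
      if (ln == "restriction") restr <- ch
      else if (ln != "annotation") {
        stop_toxowl(paste0("unsupported construct xs:", ln, " at path ", path),
                    "toxowl_unsupported_construct")
      }
    }
    if (is.null(restr)) {
      stop_toxowl(paste0("xs:simpleType without restriction at path ", path),
                  "toxowl_unsupported_construct")
    }
    base <- xml2::xml_attr(restr, "base")
    kind <- .xsd_kind_map[base]
    if (is.na(kind)) {
      stop_toxowl(paste0("unsupported restriction base ", base, " at path ",
                         path), "toxowl_unsupported_construct")
    }
    enum <- character(0)
    for (f in xml2::xml_children(restr)) {
      ln <- local_name(f)
      if (ln == "enumeration") enum <- c(enum, xml2::xml_attr(f, "value"))
      else if (ln != "annotation") {
        stop_toxowl(paste0("unsupported facet xs:", ln, " at path ", path),
                    "toxowl_unsupported_construct")
      }
    }
    if (length(enum) > 0 && kind != "string") {
      stop_toxowl(paste0("enumeration on non-string base at path ", path),
                  "toxowl_parse_error")
    }
    list(kind = unname(kind), enum = if (length(enum)) enum else NULL)
  }

  process_element <- function(node, parent_path, depth, type_stack) {
    nm <- xml2::xml_attr(node, "name")
    if (is.na(nm)) {
      stop_toxowl(paste0("unsupported construct: xs:element without a name ",
                         "(element references are not supported) under ",
                         if (nzchar(parent_path)) parent_path else "<root>"),
                  "toxowl_unsupported_construct")
    }
    path <- if (nzchar(parent_path)) paste(parent_path, nm, sep = "/") else nm
    occ <- parse_occurs(node)

    type_attr <- xml2::xml_attr(node, "type")
    inline <- keep(as.list(xml2::xml_children(node)),
                   ~ local_name(.x) %in% c("complexType", "simpleType"))
    for (ch in xml2::xml_children(node)) {
      ln <- local_name(ch)
      if (!ln %in% c("complexType", "simpleType", "annotation")) {
        stop_toxowl(paste0("unsupported construct xs:", ln, " at path ", path),
                    "toxowl_unsupported_construct")
      }
    }

    emit_leaf <- function(kind, enum = NULL) {
      add_row(path = path, name = nm, parent_path = parent_path,
              depth = depth, value_kind = kind, enumeration = list(enum),
              min_occurs = occ$min, max_occurs = occ$max)
    }
    emit_complex_from <- function(ct_node) {
      elems <- group_elements(ct_node, path)
      if (length(elems) == 0) {
        # Empty complex content carries no fields: recorded as a string leaf
        # so that value_kind = complex holds exactly when children exist.
        emit_leaf("string")
        return(invisible())
      }
      add_row(path = path, name = nm, parent_path = parent_path,
              depth = depth, value_kind = "complex", enumeration = list(NULL),
              min_occurs = occ$min, max_occurs = occ$max)
      for (e in elems) process_element(e, path, depth + 1L, type_stack)
    }

    if (!is.na(type_attr)) {
      if (length(inline) > 0) {
        stop_toxowl(paste0("element with both type attribute and inline type ",
                           "at path ", path), "toxowl_parse_error")
      }
      kind <- .xsd_kind_map[type_attr]
      if (!is.na(kind)) {
        emit_leaf(unname(kind))
      } else {
        tdef <- named_types[[type_attr]]
        if (is.null(tdef)) {
          stop_toxowl(paste0("unknown type ", type_attr, " at path ", path),
                      "toxowl_parse_error")
        }
        if (type_attr %in% type_stack) {
          stop_toxowl(paste0("recursive type ", type_attr, " at path ", path),
                      "toxowl_parse_error")
        }
        if (local_name(tdef) == "complexType") {
          old <- type_stack; type_stack <- c(type_stack, type_attr)
          emit_complex_from(tdef)
          type_stack <- old
        } else {
          st <- parse_simple(tdef, path)
          emit_leaf(st$kind, st$enum)
        }
      }
    } else if (length(inline) == 1) {
      if (local_name(inline[[1]]) == "complexType") {
        emit_complex_from(inline[[1]])
      } else {
        st <- parse_simple(inline[[1]], path)
        emit_leaf(st$kind, st$enum)
      }
    } else if (length(inline) > 1) {
      stop_toxowl(paste0("multiple inline types at path ", path),
                  "toxowl_parse_error")
    } else {
      emit_leaf("string")
    }
    invisible()
  }

  for (k in kids) {
    if (local_name(k) == "element") process_element(k, "", 1L, character(0))
  }

  fields <- bind_rows(map(rows$tab, as_tibble))
  if (nrow(fields) == 0) {
    fields <- tibble(path = character(0), name = character(0),
                     parent_path = character(0), depth = integer(0),
                     value_kind = character(0), enumeration = list(),
                     min_occurs = integer(0), max_occurs = numeric(0))
  }
  dup <- fields$path[duplicated(fields$path)]
  if (length(dup) > 0) {
    stop_toxowl(paste0("duplicate field path(s): ",
                       paste(unique(dup), collapse = ", ")),
                "toxowl_parse_error")
  }
  structure(list(fields = fields), class = "schema_graph")
}

#' Field table of a schema graph
#'
#' @param graph A `schema_graph` from [parse_schema()].
#' @return A tibble with one row per declared field, in document order.
#' @export
schema_fields <- function(graph) {
  stopifnot(inherits(graph, "schema_graph"))
  graph$fields
}

#' @export
print.schema_graph <- function(x, ...) {
  f <- x$fields
  cat("<schema_graph> ", nrow(f), " fields, max depth ",
      if (nrow(f)) max(f$depth) else 0, "\n", sep = "")
  if (nrow(f)) {
    print(select(f, "path", "value_kind", "max_occurs"), n = 10)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.schema_graph <- function(x, ...) schema_fields(x)

#' Names occurring at more than one path
#'
#' Fields with the same terminal name in different contexts are the ambiguity
#' the rename rules exist to resolve (e.g. a `Results` record appearing both
#' under a test and under a treatment group means two semantically different
#' record types that must not collapse into one ontology class).
#'
#' @param graph A `schema_graph`.
#' @return A tibble with columns `name`, `n_paths` and `paths` (list column of
#'   character vectors), one row per name used at two or more distinct paths;
#'   zero rows when every terminal name is unique.
#' @examples
#' g <- parse_schema(toxowl_example("toxml-mini.xsd"))
#' ambiguous_names(g)
#' @export
ambiguous_names <- function(graph) {
  stopifnot(inherits(graph, "schema_graph"))
  schema_fields(graph) |>
    summarise(paths = list(sort(.data$path)), .by = "name") |>
    mutate(n_paths = lengths(.data$paths)) |>
    filter(.data$n_paths >= 2L) |>
    arrange(.data$name) |>
    select("name", "n_paths", "paths")
}

#' Serialize a schema graph back to schema text
#'
#' Writes the graph as an XSD document in the same subset [parse_schema()]
#' reads, with all types inline and anonymous. Re-parsing the output yields a
#' graph with an identical field table (the round-trip property the test
#' suite asserts).
#'
#' @param graph A `schema_graph`.
#' @return A single string containing the XSD document.
#' @export
emit_schema <- function(graph) {
  stopifnot(inherits(graph, "schema_graph"))
  f <- schema_fields(graph)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  occurs_attr <- function(row) {
    a <- ""
    if (row$min_occurs != 1L) a <- paste0(a, ' minOccurs="', row$min_occurs, '"')
    if (row$max_occurs != 1) {
      a <- paste0(a, ' maxOccurs="',
                  if (is.infinite(row$max_occurs)) "unbounded"
                  else format(row$max_occurs, scientific = FALSE), '"')
    }
    a
  }
  type_attr <- c(string = "xs:string", integer = "xs:integer",
                 decimal = "xs:decimal")
  emit_field <- function(path, indent) {
    row <- f[f$path == path, ]
    pad <- strrep("  ", indent)
    occ <- occurs_attr(row)
    kids <- f$path[f$parent_path == path]
    enum <- row$enumeration[[1]]
    if (row$value_kind == "complex") {
      c(paste0(pad, '<xs:element name="', esc(row$name), '"', occ, ">"),
        paste0(pad, "  <xs:complexType>"),
        paste0(pad, "    <xs:sequence>"),
        unlist(map(kids, emit_field, indent = indent + 3L)),
        paste0(pad, "    </xs:sequence>"),
        paste0(pad, "  </xs:complexType>"),
        paste0(pad, "</xs:element>"))
    } else if (!is.null(enum)) {
      c(paste0(pad, '<xs:element name="', esc(row$name), '"', occ, ">"),
        paste0(pad, "  <xs:simpleType>"),
        paste0(pad, '    <xs:restriction base="xs:string">'),
        paste0(pad, '      <xs:enumeration value="', esc(enum), '"/>'),
        paste0(pad, "    </xs:restriction>"),
        paste0(pad, "  </xs:simpleType>"),
        paste0(pad, "</xs:element>"))
    } else {
      paste0(pad, '<xs:element name="', esc(row$name), '" type="',
             type_attr[[row$value_kind]], '"', occ, "/>")
    }
  }
  top <- f$path[f$parent_path == ""]
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             paste0('<xs:schema xmlns:xs="', XSD_NS, '">'),
             unlist(map(top, emit_field, indent = 1L)),
             "</xs:schema>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Path to a bundled example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
toxowl_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "toxowl")))
  }
  path <- system.file("extdata", file, package = "toxowl")
  if (!nzchar(path)) {
    stop_toxowl(paste0("no bundled example file '", file, "'"),
                "toxowl_error")
  }
  path
}

#' Generate a random toy schema
#'
#' Emits a seeded random XSD document in the supported subset: one complex
#' root element to which further elements are attached at random, each either
#' a nested complex record or a string/integer/decimal leaf (string leaves
#' occasionally carry a small enumeration). Used by the property-style tests:
#' the returned text carries the generator's own bookkeeping so parsed output
#' can be checked against an independent tally.
#'
#' @param n_fields Total number of element declarations (>= 1).
#' @param seed Integer seed; the same seed always yields the same document.
#' @param p_leaf Probability that a new element is a leaf rather than a
#'   nested record.
#' @param p_enum Probability that a string leaf carries an enumeration.
#' @param name_pool Candidate element names; sampled with replacement so the
#'   same name can recur in different contexts (the ambiguity case).
#' @return A single string of XSD text, with attribute `fields`: a tibble
#'   (`path`, `name`, `value_kind`) of what the generator planted.
#' @export
random_schema <- function(n_fields, seed, p_leaf = 0.55, p_enum = 0.2,
                          name_pool = c("Study", "Test", "Results", "Dose",
                                        "Animal", "Name", "Background",
                                        "Group", "Outcome", "Compound",
                                        "Species", "Weight", "Duration",
                                        "Route", "Organ")) {
  stopifnot(n_fields >= 1)
  with_seed(seed, {
    nodes <- tibble(path = character(0), name = character(0),
                    value_kind = character(0), enum = list())
    pick_name <- function(parent_path) {
      sibs <- nodes$name[dirname_path(nodes$path) == parent_path]
      repeat {
        nm <- sample(name_pool, 1)
        if (!nm %in% sibs) return(nm)
        if (all(name_pool %in% sibs)) return(paste0(nm, nrow(nodes)))
      }
    }
    root_name <- sample(name_pool, 1)
    nodes <- add_row(nodes, path = root_name, name = root_name,
                     value_kind = "complex", enum = list(NULL))
    while (nrow(nodes) < n_fields) {
      parents <- nodes$path[nodes$value_kind == "complex"]
      parent <- if (length(parents) == 1) parents else sample(parents, 1)
      nm <- pick_name(parent)
      leaf <- runif(1) < p_leaf
      kind <- if (leaf) sample(c("string", "integer", "decimal"),
                               1, prob = c(0.6, 0.25, 0.15)) else "complex"
      enum <- NULL
      if (kind == "string" && runif(1) < p_enum) {
        enum <- paste0("V", seq_len(sample(2:4, 1)))
      }
      nodes <- add_row(nodes, path = paste(parent, nm, sep = "/"), name = nm,
                       value_kind = kind, enum = list(enum))
    }
    # A complex node that never received children cannot survive as complex.
    childless <- nodes$value_kind == "complex" &
      !nodes$path %in% dirname_path(nodes$path)
    nodes$value_kind[childless] <- "string"

    fields <- tibble(path = nodes$path, name = nodes$name,
                     parent_path = dirname_path(nodes$path),
                     depth = lengths(path_parts(nodes$path)),
                     value_kind = nodes$value_kind,
                     enumeration = nodes$enum,
                     min_occurs = 1L, max_occurs = 1)
    g <- structure(list(fields = fields), class = "schema_graph")
    structure(emit_schema(g),
              fields = select(fields, "path", "name", "value_kind"))
  })
}

dirname_path <- function(paths) {
  vapply(paths, parent_of, character(1), USE.NAMES = FALSE)
}
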