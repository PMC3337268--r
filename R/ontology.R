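NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"

DEFAULT_BASE_IRI <- "http://example.org/toxowl"

.xsd_literal <- c(string = paste0(NS_XSD, "string"),
                  integer = paste0(NS_XSD, "integer"),
                  decimal = paste0(NS_XSD, "decimal"))

#' Create an empty ontology model
#'
#' The in-memory representation of an OWL-DL ontology as this package uses
#' it: named classes, object properties with class-set domains and ranges
#' (a set of more than one class is serialized as an `owl:unionOf`
#' expression), datatype properties with a literal range, explicit subclass
#' axioms, and optional human-readable comments. Entity IRIs are
#' `base_iri#Label`. Blank-node-free apart from the RDF collection backbone
#' of union expressions, so two models are equal exactly when their
#' canonical serializations are byte-identical.
#'
#' @param base_iri Namespace IRI (without the trailing `#`) under which all
#'   entity IRIs are minted.
#' @return An empty `ontology_model` object.
#' @seealso [add_class()], [emit_owl()], [check_structure()],
#'   [ontology_stats()]
#' @export
ontology_model <- function(base_iri = DEFAULT_BASE_IRI) {
  stopifnot(is.character(base_iri), length(base_iri) == 1, nzchar(base_iri))
  base_iri <- sub("#$", "", base_iri)
  structure(
    list(
      base_iri = base_iri,
      classes = tibble(label = character(0), comment = character(0)),
      object_properties = tibble(label = character(0), domain = list(),
                                 range = list(), comment = character(0)),
      datatype_properties = tibble(label = character(0), domain = list(),
                                   datatype = character(0),
                                   comment = character(0)),
      subclass_axioms = tibble(child = character(0), parent = character(0))
    ),
    class = "ontology_model"
  )
}

#' Add entities to an ontology model
#'
#' Pipe-friendly mutators. Re-adding an identical entity is a no-op;
#' re-adding a label with conflicting content is an error.
#'
#' @param model An `ontology_model`.
#' @param label Entity label (UpperCamelCase for classes, `hasX` for
#'   properties by this package's conventions; not enforced here).
#' @param comment Optional human-readable annotation.
#' @param domain,range Character vectors of class labels; a domain or range
#'   with more than one label means the union of those classes.
#' @param datatype Literal range of a datatype property: `"string"`,
#'   `"integer"` or `"decimal"`.
#' @param child,parent Class labels of a subclass axiom `child` \eqn{\subset}
#'   `parent`.
#' @return The updated model.
#' @name ontology-mutators
NULL

#' @rdname ontology-mutators
#' @export
add_class <- function(model, label, comment = NA_character_) {
  stopifnot(inherits(model, "ontology_model"))
  for (i in seq_along(label)) {
    cm <- if (length(comment) >= i) comment[[i]] else NA_character_
    hit <- which(model$classes$label == label[[i]])
    if (length(hit)) {
      if (!is.na(cm) && is.na(model$classes$comment[hit])) {
        model$classes$comment[hit] <- cm
      }
      next
    }
    model$classes <- add_row(model$classes, label = label[[i]], comment = cm)
  }
  model
}

#' @rdname ontology-mutators
#' @export
add_object_property <- function(model, label, domain, range,
                                comment = NA_character_) {
  stopifnot(inherits(model, "ontology_model"), length(label) == 1)
  domain <- sort(unique(as.character(domain)))
  range <- sort(unique(as.character(range)))
  hit <- which(model$object_properties$label == label)
  if (length(hit)) {
    model$object_properties$domain[[hit]] <-
      sort(union(model$object_properties$domain[[hit]], domain))
    model$object_properties$range[[hit]] <-
      sort(union(model$object_properties$range[[hit]], range))
    return(model)
  }
  model$object_properties <- add_row(model$object_properties, label = label,
                                     domain = list(domain),
                                     range = list(range), comment = comment)
  model
}

#' @rdname ontology-mutators
#' @export
add_datatype_property <- function(model, label, domain, datatype = "string",
                                  comment = NA_character_) {
  stopifnot(inherits(model, "ontology_model"), length(label) == 1,
            datatype %in% names(.xsd_literal))
  domain <- sort(unique(as.character(domain)))
  hit <- which(model$datatype_properties$label == label)
  if (length(hit)) {
    if (!identical(model$datatype_properties$datatype[[hit]], datatype)) {
      stop_toxowl(paste0("datatype property ", label,
                         " re-added with conflicting literal type"),
                  "toxowl_collision_error")
    }
    model$datatype_properties$domain[[hit]] <-
      sort(union(model$datatype_properties$domain[[hit]], domain))
    return(model)
  }
  model$datatype_properties <- add_row(model$datatype_properties,
                                       label = label, domain = list(domain),
                                       datatype = datatype, comment = comment)
  model
}

#' @rdname ontology-mutators
#' @export
add_subclass <- function(model, child, parent) {
  stopifnot(inherits(model, "ontology_model"),
            length(child) == length(parent))
  for (i in seq_along(child)) {
    dup <- model$subclass_axioms$child == child[[i]] &
      model$subclass_axioms$parent == parent[[i]]
    if (any(dup)) next
    model$subclass_axioms <- add_row(model$subclass_axioms,
                                     child = child[[i]], parent = parent[[i]])
  }
  model
}

canonicalize_ontology <- function(model) {
  model$classes <- arrange(model$classes, .data$label)
  model$object_properties <- model$object_properties |>
    mutate(domain = map(.data$domain, sort), range = map(.data$range, sort)) |>
    arrange(.data$label)
  model$datatype_properties <- model$datatype_properties |>
    mutate(domain = map(.data$domain, sort)) |>
    arrange(.data$label)
  model$subclass_axioms <- arrange(model$subclass_axioms,
                                   .data$child, .data$parent)
  model
}

#' Test two ontology models for equality of information content
#'
#' Compares base IRI, class set (with comments), property records (labels,
#' domain/range sets, literal types) and subclass axioms, ignoring insertion
#' order.
#'
#' @param a,b `ontology_model` objects.
#' @return `TRUE` or `FALSE`.
#' @export
ontology_equal <- function(a, b) {
  a <- canonicalize_ontology(a); b <- canonicalize_ontology(b)
  identical(a$base_iri, b$base_iri) &&
    identical(a$classes, b$classes) &&
    identical(a$subclass_axioms, b$subclass_axioms) &&
    identical(select(a$object_properties, -"comment"),
              select(b$object_properties, -"comment")) &&
    identical(select(a$datatype_properties, -"comment"),
              select(b$datatype_properties, -"comment"))
}

#' Structural consistency check
#'
#' Validates the model invariants: every label referenced by a property
#' domain/range or a subclass axiom must be a declared class, labels are
#' unique per entity category, and the subclass relation is acyclic. These
#' structural checks are the package's consistency gate; the ontologies
#' produced here contain no constructs that would require tableau (DL)
#' reasoning beyond them.
#'
#' @param model An `ontology_model`.
#' @return A tibble of issues with columns `rule`, `label` and `detail`;
#'   zero rows means the model is structurally valid.
#' @export
check_structure <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  issues <- list()
  note <- function(rule, label, detail) {
    issues[[length(issues) + 1L]] <<- tibble(rule = rule, label = label,
                                             detail = detail)
  }
  declared <- model$classes$label

  dup <- unique(declared[duplicated(declared)])
  for (d in dup) note("duplicate_class", d, "class label declared twice")
  for (tab in c("object_properties", "datatype_properties")) {
    labs <- model[[tab]]$label
    for (d in unique(labs[duplicated(labs)])) {
      note("duplicate_property", d, paste0("label declared twice in ", tab))
    }
  }

  for (i in seq_len(nrow(model$object_properties))) {
    p <- model$object_properties[i, ]
    for (d in setdiff(p$domain[[1]], declared)) {
      note("dangling_domain", p$label, paste0("domain class ", d,
                                              " is not declared"))
    }
    for (r in setdiff(p$range[[1]], declared)) {
      note("dangling_range", p$label, paste0("range class ", r,
                                             " is not declared"))
    }
  }
  for (i in seq_len(nrow(model$datatype_properties))) {
    p <- model$datatype_properties[i, ]
    for (d in setdiff(p$domain[[1]], declared)) {
      note("dangling_domain", p$label, paste0("domain class ", d,
                                              " is not declared"))
    }
  }

  ax <- model$subclass_axioms
  for (lab in setdiff(unique(c(ax$child, ax$parent)), declared)) {
    note("dangling_subclass", lab,
         "subclass axiom references an undeclared class")
  }

  # Cycle detection over the child -> parent edges (iterative DFS).
  adj <- split(ax$parent, ax$child)
  state <- new.env(parent = emptyenv())
  cycle_found <- FALSE
  visit <- function(node, stack) {
    if (cycle_found) return()
    st <- get0(node, envir = state, ifnotfound = "new")
    if (identical(st, "done")) return()
    if (identical(st, "open")) {
      cyc <- c(stack[which(stack == node):length(stack)], node)
      note("subclass_cycle", node,
           paste0("cycle: ", paste(cyc, collapse = " < ")))
      cycle_found <<- TRUE
      return()
    }
    assign(node, "open", envir = state)
    for (p in adj[[node]] %||% character(0)) visit(p, c(stack, node))
    assign(node, "done", envir = state)
  }
  for (n in unique(ax$child)) visit(n, character(0))

  if (length(issues) == 0) {
    return(tibble(rule = character(0), label = character(0),
                  detail = character(0)))
  }
  bind_rows(issues)
}

#' Entity and axiom counts of an ontology
#'
#' @param model An `ontology_model`.
#' @return An `ontology_stats` list: `n_classes`, `n_object_properties`,
#'   `n_datatype_properties`, `n_subclass_axioms`, and `subclass_counts`, a
#'   named integer vector giving for each parent class its number of
#'   *direct* subclasses.
#' @examples
#' ontology_stats(build_endpoint_ontology())$subclass_counts[["ToxicityStudyType"]]
#' @export
ontology_stats <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  ax <- model$subclass_axioms
  counts <- if (nrow(ax)) {
    tab <- table(ax$parent)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(
    list(n_classes = nrow(model$classes),
         n_object_properties = nrow(model$object_properties),
         n_datatype_properties = nrow(model$datatype_properties),
         n_subclass_axioms = nrow(ax),
         subclass_counts = counts),
    class = "ontology_stats"
  )
}

#' @export
print.ontology_stats <- function(x, ...) {
  cat("<ontology_stats> classes:", x$n_classes,
      " object props:", x$n_object_properties,
      " datatype props:", x$n_datatype_properties,
      " subclass axioms:", x$n_subclass_axioms, "\n")
  if (length(x$subclass_counts)) {
    cat("direct subclasses per parent:\n")
    print(x$subclass_counts)
  }
  invisible(x)
}

#' @export
print.ontology_model <- function(x, ...) {
  cat("<ontology_model> base IRI:", x$base_iri, "\n")
  print(ontology_stats(x))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.ontology_model <- function(x, ...) {
  s <- ontology_stats(x)
  tibble(base_iri = x$base_iri, n_classes = s$n_classes,
         n_object_properties = s$n_object_properties,
         n_datatype_properties = s$n_datatype_properties,
         n_subclass_axioms = s$n_subclass_axioms)
}

#' @export
tidy.ontology_model <- function(x, ...) {
  m <- canonicalize_ontology(x)
  bind_rows(
    mutate(m$classes, kind = "class", domain = list(character(0)),
           range = list(character(0))),
    mutate(m$object_properties, kind = "object_property"),
    m$datatype_properties |>
      mutate(kind = "datatype_property",
             range = map(.data$datatype, ~ .x)) |>
      select(-"datatype"),
    m$subclass_axioms |>
      mutate(kind = "subclass_axiom", label = .data$child,
             domain = map(.data$child, ~ .x),
             range = map(.data$parent, ~ .x),
             comment = NA_character_) |>
      select(-"child", -"parent")
  ) |>
    select("kind", "label", "domain", "range", "comment")
}

#' Plot an ontology model summary
#'
#' With `type = "summary"`, a bar chart of entity counts; with
#' `type = "subclasses"`, direct-subclass counts per parent class.
#'
#' @param object An `ontology_model`.
#' @param type `"summary"` or `"subclasses"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_col coord_flip labs
#' @export
autoplot.ontology_model <- function(object, type = c("summary", "subclasses"),
                                    ...) {
  type <- match.arg(type)
  s <- ontology_stats(object)
  if (type == "summary") {
    df <- tibble(
      entity = factor(c("classes", "object properties",
                        "datatype properties", "subclass axioms"),
                      levels = c("classes", "object properties",
                                 "datatype properties", "subclass axioms")),
      n = c(s$n_classes, s$n_object_properties, s$n_datatype_properties,
            s$n_subclass_axioms))
    ggplot(df, aes(x = .data$entity, y = .data$n)) +
      geom_col() +
      labs(x = NULL, y = "count", title = "Ontology composition")
  } else {
    df <- tibble(parent = names(s$subclass_counts),
                 n = as.integer(s$subclass_counts))
    ggplot(df, aes(x = stats::reorder(.data$parent, .data$n), y = .data$n)) +
      geom_col() +
      coord_flip() +
      labs(x = NULL, y = "direct subclasses",
           title = "Direct subclasses per parent class")
  }
}
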