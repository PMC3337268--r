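#' Declarative schema-to-ontology conversion rules
#'
#' A ruleset captures the expert decisions the conversion cannot infer from
#' structure alone: which wrapper elements are meaningless containers, which
#' ambiguous names must be renamed in which context, which string leaves are
#' promoted to named classes, which explicit IS-A links to assert, and which
#' raw labels are spellings of the same concept.
#'
#' @param containers Character vector of container elements to elide, given
#'   either as bare element names (matched at any path) or full
#'   slash-joined paths. A container's children are re-attached to its
#'   parent. Only complex fields are elided.
#' @param renames Named character vector `path -> new label`, applied before
#'   label deduplication. Rename targets must be distinct.
#' @param promotions Character vector of paths of string leaves to promote
#'   to classes (enumerated leaves are promoted automatically).
#' @param subclasses Subclass assertions: a two-column object (child,
#'   parent), or a list of length-2 vectors. These are the *only* IS-A links
#'   the conversion will emit.
#' @param unify Named character vector `raw label -> canonical label`,
#'   merging spelling variants before deduplication.
#' @return A `ruleset` object.
#' @seealso [convert_schema()], [read_ruleset()], [default_ruleset()]
#' @export
ruleset <- function(containers = character(0), renames = character(0),
                    promotions = character(0), subclasses = NULL,
                    unify = character(0)) {
  renames <- unlist(renames) %||% character(0)
  unify <- unlist(unify) %||% character(0)
  if (length(renames) > 0 && is.null(names(renames))) {
    stop_toxowl("renames must be a named map path -> label",
                "toxowl_rule_error")
  }
  if (anyDuplicated(unname(renames))) {
    dups <- unique(renames[duplicated(renames)])
    stop_toxowl(paste0("rename targets must be unique; duplicated: ",
                       paste(dups, collapse = ", ")), "toxowl_rule_error")
  }
  if (is.null(subclasses)) {
    subclasses <- tibble(child = character(0), parent = character(0))
  } else if (is.data.frame(subclasses)) {
    subclasses <- tibble(child = as.character(subclasses[[1]]),
                         parent = as.character(subclasses[[2]]))
  } else {
    subclasses <- tibble(
      child = map_chr(subclasses, ~ as.character(.x)[[1]]),
      parent = map_chr(subclasses, ~ as.character(.x)[[2]]))
  }
  structure(
    list(containers = as.character(containers), renames = renames,
         promotions = as.character(promotions), subclasses = subclasses,
         unify = unify),
    class = "ruleset"
  )
}

#' @export
print.ruleset <- function(x, ...) {
  cat("<ruleset>",
      length(x$containers), "containers,",
      length(x$renames), "renames,",
      length(x$promotions), "promotions,",
      nrow(x$subclasses), "subclass assertions,",
      length(x$unify), "unifications\n")
  invisible(x)
}

#' Read a ruleset from a YAML file
#'
#' Accepts keys `containers`, `renames`, `promotions`, `subclasses` (a list
#' of `[child, parent]` pairs or `{child:, parent:}` maps) and `unify`.
#' Missing keys default to empty.
#'
#' @param path Path to the YAML ruleset file.
#' @return A `ruleset`.
#' @examples
#' read_ruleset(toxowl_example("default.rules.yaml"))
#' @export
read_ruleset <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_toxowl(paste0("cannot read ruleset: ", conditionMessage(e)),
                "toxowl_rule_error", parent = e)
  })
  subs <- cfg$subclasses
  if (!is.null(subs)) {
    subs <- map(subs, function(s) {
      if (!is.null(names(s)) && all(c("child", "parent") %in% names(s))) {
        c(s$child, s$parent)
      } else {
        unlist(s)
      }
    })
  }
  ruleset(containers = cfg$containers %||% character(0),
          renames = cfg$renames %||% character(0),
          promotions = cfg$promotions %||% character(0),
          subclasses = subs,
          unify = cfg$unify %||% character(0))
}

#' The shipped default ruleset
#'
#' Encodes the expert rule instances this toolchain was built around:
#' `Tests` and `Compounds` are containers; the `Results` record under a
#' treatment group is renamed `TreatmentResults` to resolve its ambiguity
#' with per-test results; `ChronicStudies` is asserted a subclass of
#' `Study`.
#'
#' @return A `ruleset`.
#' @export
default_ruleset <- function() {
  ruleset(
    containers = c("Tests", "Compounds"),
    renames = c("Study/TreatmentGroup/Results" = "TreatmentResults"),
    subclasses = list(c("ChronicStudies", "Study"))
  )
}

#' Name of the object property linking a nesting tuple
#'
#' For fields `F2` nested in `F1`, the generated relation is `has<F2>`:
#' `(Study, Background)` gives `hasBackground`.
#'
#' @param parent_label,child_label Non-empty class labels.
#' @return The property name, `"has"` + the child label in UpperCamelCase.
#' @export
derive_object_property_name <- function(parent_label, child_label) {
  stopifnot(nzchar(parent_label), nzchar(child_label))
  paste0("has", to_upper_camel(child_label))
}

is_container <- function(path, name, rules) {
  path %in% rules$containers | name %in% rules$containers
}

#' Classify every schema field for conversion
#'
#' Assigns each field its disposition: complex records become ontology
#' `class`es; string/numeric leaves become `datatype_property`s; leaves with
#' an enumeration or explicitly listed in the promotions rule become
#' `promoted_class`es (a named concept replacing a free string); fields
#' matching the containers rule are `elided_container`s. Every field of the
#' graph receives exactly one disposition.
#'
#' @param graph A `schema_graph`.
#' @param rules A `ruleset`.
#' @return A tibble with columns `path`, `name`, `disposition`.
#' @export
classify_fields <- function(graph, rules = default_ruleset()) {
  stopifnot(inherits(graph, "schema_graph"), inherits(rules, "ruleset"))
  f <- schema_fields(graph)
  bad_promo <- intersect(rules$promotions,
                         f$path[f$value_kind != "string"])
  if (length(bad_promo) > 0) {
    stop_toxowl(paste0("promotion rule points at non-string field(s): ",
                       paste(bad_promo, collapse = ", ")),
                "toxowl_rule_error")
  }
  missing_promo <- setdiff(rules$promotions, f$path)
  if (length(missing_promo) > 0) {
    stop_toxowl(paste0("promotion path(s) not in schema: ",
                       paste(missing_promo, collapse = ", ")),
                "toxowl_rule_error")
  }
  f |>
    mutate(
      has_enum = !map_lgl(.data$enumeration, is.null),
      disposition = case_when(
        .data$value_kind == "complex" &
          is_container(.data$path, .data$name, rules) ~ "elided_container",
        .data$value_kind == "complex" ~ "class",
        .data$path %in% rules$promotions | .data$has_enum ~ "promoted_class",
        TRUE ~ "datatype_property"
      )
    ) |>
    select("path", "name", "disposition")
}

#' Convert a schema graph into an OWL ontology
#'
#' The lifting procedure at the heart of the package. Complex records become
#' classes, deduplicated by final label, and every surviving nesting tuple
#' `(F1, F2)` yields one object property `has<F2>` with domain `F1` and
#' range `F2` -- a class nested under several parents gets a single property
#' whose domain is the union of those parent classes. Containers are elided
#' with their children re-attached to the container's parent. String and
#' numeric leaves become `has<X>` datatype properties on their parent class,
#' except enumerated or explicitly promoted leaves, which become named
#' classes linked by an object property. Renames and label unifications are
#' applied before deduplication, and the only IS-A links in the output are
#' the ruleset's explicit subclass assertions: the result is deliberately
#' flat, because XML nesting does not follow the IS-A semantics of OWL
#' subclassing.
#'
#' @param graph A `schema_graph` from [parse_schema()].
#' @param rules A `ruleset`; defaults to [default_ruleset()].
#' @param base_iri Namespace for the generated ontology entities.
#' @return A `schema_conversion` list with elements `ontology` (an
#'   [ontology_model()]) and `report` (a tibble accounting for 100% of the
#'   input fields: `path`, `name`, `disposition`, `label`, plus attributes
#'   `renames_applied` and `warnings`).
#' @examples
#' g <- parse_schema(toxowl_example("toxml-mini.xsd"))
#' conv <- convert_schema(g, default_ruleset())
#' conv$ontology
#' dplyr::count(conv$report, disposition)
#' @export
convert_schema <- function(graph, rules = default_ruleset(),
                           base_iri = DEFAULT_BASE_IRI) {
  stopifnot(inherits(graph, "schema_graph"), inherits(rules, "ruleset"))
  f <- schema_fields(graph)
  warnings <- character(0)

  missing_ren <- setdiff(names(rules$renames), f$path)
  if (length(missing_ren) > 0) {
    stop_toxowl(paste0("rename path(s) not in schema: ",
                       paste(missing_ren, collapse = ", ")),
                "toxowl_rule_error")
  }
  path_containers <- grep("/", rules$containers, fixed = TRUE, value = TRUE)
  missing_cont <- setdiff(path_containers, f$path)
  if (length(missing_cont) > 0) {
    stop_toxowl(paste0("container path(s) not in schema: ",
                       paste(missing_cont, collapse = ", ")),
                "toxowl_rule_error")
  }

  rep0 <- classify_fields(graph, rules)
  f <- left_join(f, rep0, by = c("path", "name"))

  # Final labels: rename (keyed by path), then unification, then case
  # normalization.
  raw <- ifelse(f$path %in% names(rules$renames),
                rules$renames[f$path], f$name)
  unified <- ifelse(raw %in% names(rules$unify), rules$unify[raw], raw)
  f$label <- to_upper_camel(unified)
  f$raw_label <- raw

  # Merging identical labels from different paths is the intended design
  # (one class, many relations); a collision between *originally distinct*
  # names is an error unless the ruleset unified them explicitly.
  class_rows <- f[f$disposition %in% c("class", "promoted_class"), ]
  for (L in unique(class_rows$label)) {
    grp <- class_rows[class_rows$label == L, ]
    origins <- unique(grp$name)
    if (length(origins) > 1 &&
        !all(grp$raw_label %in% names(rules$unify))) {
      stop_toxowl(paste0("label collision on '", L, "' between paths ",
                         paste(grp$path, collapse = " and "),
                         " (originals: ", paste(origins, collapse = ", "),
                         "); add a rename or a unify rule"),
                  "toxowl_collision_error")
    }
  }

  # Effective parent: nearest ancestor that is not an elided container.
  disp_of <- stats::setNames(f$disposition, f$path)
  label_of <- stats::setNames(f$label, f$path)
  effective_parent <- function(path) {
    p <- parent_of(path)
    while (nzchar(p) && disp_of[[p]] == "elided_container") p <- parent_of(p)
    p
  }
  f$eff_parent <- vapply(f$path, effective_parent, character(1))

  m <- ontology_model(base_iri)
  cls <- f[f$disposition == "class", ]
  for (i in seq_len(nrow(cls))) m <- add_class(m, cls$label[[i]])
  promoted <- f[f$disposition == "promoted_class", ]
  for (i in seq_len(nrow(promoted))) {
    enum <- schema_fields(graph)$enumeration[[
      which(schema_fields(graph)$path == promoted$path[[i]])]]
    cm <- if (!is.null(enum)) {
      paste0("Allowed values: ", paste(enum, collapse = ", "))
    } else NA_character_
    m <- add_class(m, promoted$label[[i]], cm)
  }

  link_rows <- f[f$disposition %in% c("class", "promoted_class") &
                   nzchar(f$eff_parent), ]
  for (i in seq_len(nrow(link_rows))) {
    r <- link_rows[i, ]
    parent_label <- label_of[[r$eff_parent]]
    m <- add_object_property(
      m, derive_object_property_name(parent_label, r$label),
      domain = parent_label, range = r$label)
  }

  dt_map <- c(string = "string", integer = "integer", decimal = "decimal")
  dt_rows <- f[f$disposition == "datatype_property", ]
  for (i in seq_len(nrow(dt_rows))) {
    r <- dt_rows[i, ]
    dom <- if (nzchar(r$eff_parent)) label_of[[r$eff_parent]]
           else character(0)
    prop <- paste0("has", r$label)
    m <- tryCatch(
      add_datatype_property(m, prop, dom, dt_map[[r$value_kind]]),
      toxowl_collision_error = function(e) {
        warnings <<- c(warnings, paste0(
          "datatype property ", prop, " carries conflicting literal types ",
          "across paths; keeping the first declaration"))
        m
      })
  }

  declared <- m$classes$label
  dangling <- setdiff(unique(c(rules$subclasses$child,
                               rules$subclasses$parent)), declared)
  if (length(dangling) > 0) {
    stop_toxowl(paste0("subclass assertion references undeclared class(es): ",
                       paste(dangling, collapse = ", ")),
                "toxowl_rule_error")
  }
  m <- add_subclass(m, rules$subclasses$child, rules$subclasses$parent)

  report <- select(f, "path", "name", "disposition", "label")
  ren_paths <- names(rules$renames) %||% character(0)
  attr(report, "renames_applied") <-
    tibble(path = ren_paths, from = terminal_name(ren_paths),
           to = unname(rules$renames) %||% character(0))
  attr(report, "warnings") <- warnings
  structure(list(ontology = m, report = report),
            class = "schema_conversion")
}

#' @export
print.schema_conversion <- function(x, ...) {
  cat("<schema_conversion>\n")
  print(count(x$report, .data$disposition))
  print(x$ontology)
  invisible(x)
}

#' @export
tidy.schema_conversion <- function(x, ...) x$report

#' @export
glance.schema_conversion <- function(x, ...) {
  bind_cols(glance(x$ontology),
            tibble(n_fields = nrow(x$report),
                   n_warnings = length(attr(x$report, "warnings"))))
}

#' @rdname autoplot.ontology_model
#' @export
autoplot.schema_conversion <- function(object, ...) {
  df <- count(object$report, .data$disposition)
  ggplot(df, aes(x = stats::reorder(.data$disposition, .data$n),
                 y = .data$n)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "fields",
         title = "Field dispositions in schema conversion")
}
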