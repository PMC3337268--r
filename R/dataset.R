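NS_OT <- "http://www.opentox.org/api/1.1#"
NS_DC <- "http://purl.org/dc/elements/1.1/"

# Minimal constant slice of the OpenTox vocabulary used by the dataset
# model (the framework also defines Algorithm/Model/Validation components;
# they are namespace constants only, not modeled here).
ot <- function(x) paste0(NS_OT, x)

#' Read an SDF V2000 file into compound records
#'
#' Splits the file into `$$$$`-delimited records (record framing via
#' ChemmineR) and extracts, per record, the compound identifier, the
#' verbatim structure block (untouched, through `M  END`), and the ordered
#' `> <name>` data fields. Field values spanning several lines are joined
#' with newlines.
#'
#' @param file Path to an SDF file.
#' @param id_field Optional name of a data field to use as the compound
#'   identifier instead of the molfile title line.
#' @return A tibble with one row per record: `identifier`,
#'   `structure_block` (single string), `properties` (list column of named
#'   character vectors, in file order).
#' @examples
#' read_sdf(toxowl_example("cpdbas-toy.sdf"))
#' @export
read_sdf <- function(file, id_field = NULL) {
  if (!file.exists(file)) {
    stop_toxowl(paste0("no such SDF file: ", file), "toxowl_parse_error")
  }
  raw <- readLines(file, warn = FALSE)
  if (length(raw) == 0 || all(!nzchar(trimws(raw)))) {
    return(tibble(identifier = character(0), structure_block = character(0),
                  properties = list()))
  }
  n_delim <- sum(trimws(raw) == "$$$$")
  trailing <- if (n_delim == 0) raw
              else raw[seq_len(length(raw)) > max(which(trimws(raw) == "$$$$"))]
  if (any(nzchar(trimws(trailing)))) {
    stop_toxowl(paste0("truncated SDF record after delimiter ", n_delim,
                       ": record ", n_delim + 1L,
                       " is not terminated by $$$$"), "toxowl_parse_error")
  }
  records <- as(ChemmineR::read.SDFstr(file), "list")
  if (length(records) != n_delim) {
    stop_toxowl(paste0("SDF framing mismatch: ", n_delim, " delimiters but ",
                       length(records), " records"), "toxowl_parse_error")
  }
  out <- map(seq_along(records), function(k) {
    lines <- records[[k]]
    lines <- lines[cumsum(trimws(lines) == "$$$$") == 0]
    end_idx <- which(trimws(lines) == "M  END")
    if (length(end_idx) == 0) {
      stop_toxowl(paste0("record ", k, " has no molblock terminator M  END"),
                  "toxowl_parse_error")
    }
    end_idx <- end_idx[[1]]
    structure_block <- paste(lines[seq_len(end_idx)], collapse = "\n")
    title <- trimws(lines[[1]])
    props <- character(0)
    i <- end_idx + 1L
    while (i <= length(lines)) {
      ln <- lines[[i]]
      if (grepl("^>\\s*<.*>", ln)) {
        name <- sub("^>\\s*<\\s*([^>]*?)\\s*>.*$", "\\1", ln)
        vals <- character(0)
        i <- i + 1L
        while (i <= length(lines) && nzchar(trimws(lines[[i]])) &&
               !grepl("^>\\s*<.*>", lines[[i]])) {
          vals <- c(vals, lines[[i]])
          i <- i + 1L
        }
        if (name %in% names(props)) {
          stop_toxowl(paste0("record ", k, " declares data field '", name,
                             "' twice"), "toxowl_parse_error")
        }
        props[[name]] <- paste(vals, collapse = "\n")
      } else {
        i <- i + 1L
      }
    }
    identifier <- if (is.null(id_field)) title
                  else props[[id_field]] %||% NA_character_
    if (is.null(identifier) || is.na(identifier) || !nzchar(identifier)) {
      stop_toxowl(paste0("record ", k, " has no usable identifier",
                         if (!is.null(id_field)) {
                           paste0(" (field '", id_field, "')")
                         } else " (empty title line)"),
                  "toxowl_parse_error")
    }
    tibble(identifier = identifier, structure_block = structure_block,
           properties = list(props))
  })
  bind_rows(out)
}

#' Build an RDF-ready dataset model from compound records
#'
#' Lifts SDF records into the OpenTox dataset representation: the dataset
#' is an `ot:Dataset`, every distinct data-field name becomes an
#' `ot:Feature` with a deterministically minted IRI under the dataset IRI,
#' and every (compound, field, value) cell becomes an `ot:FeatureValue`.
#' Values are carried as raw strings; normalization (see [parse_ratio()])
#' is an opt-in, per-feature concern.
#'
#' @param records A tibble from [read_sdf()].
#' @param dataset_iri IRI of the dataset resource.
#' @param call_feature Optional name of the feature holding this dataset's
#'   carcinogenicity call (required by [query_merged()]).
#' @return A `dataset_model` with elements `dataset_iri`, `compounds`,
#'   `features` (tibble `name`, `iri`), `annotations` (tibble `feature`,
#'   `link_kind`, `target`), `values` (tibble `identifier`, `feature`,
#'   `value`) and `call_feature`.
#' @export
build_dataset <- function(records, dataset_iri, call_feature = NULL) {
  stopifnot(is.data.frame(records), is.character(dataset_iri),
            length(dataset_iri) == 1)
  dataset_iri <- sub("/$", "", dataset_iri)
  dups <- unique(records$identifier[duplicated(records$identifier)])
  if (length(dups) > 0) {
    stop_toxowl(paste0("duplicate compound identifier(s): ",
                       paste(dups, collapse = ", ")), "toxowl_parse_error")
  }
  feat_names <- unique(unlist(map(records$properties, names)))
  feat_names <- feat_names %||% character(0)
  features <- tibble(
    name = feat_names,
    iri = paste0(dataset_iri, "/feature/",
                 vapply(feat_names, utils::URLencode, character(1),
                        reserved = TRUE, USE.NAMES = FALSE)))
  values <- bind_rows(map(seq_len(nrow(records)), function(i) {
    p <- records$properties[[i]]
    if (length(p) == 0) return(NULL)
    tibble(identifier = records$identifier[[i]], feature = names(p),
           value = unname(p))
  }))
  if (nrow(records) == 0 || is.null(values) || nrow(values) == 0) {
    values <- tibble(identifier = character(0), feature = character(0),
                     value = character(0))
  }
  if (!is.null(call_feature) && !call_feature %in% features$name) {
    stop_toxowl(paste0("call feature '", call_feature,
                       "' is not a feature of this dataset"),
                "toxowl_error")
  }
  structure(
    list(dataset_iri = dataset_iri,
         compounds = select(records, "identifier", "structure_block"),
         features = features,
         annotations = tibble(feature = character(0),
                              link_kind = character(0),
                              target = character(0)),
         values = values,
         call_feature = call_feature %||% NA_character_),
    class = "dataset_model")
}

#' @export
print.dataset_model <- function(x, ...) {
  cat("<dataset_model>", x$dataset_iri, "\n ",
      nrow(x$compounds), "compounds,", nrow(x$features), "features,",
      nrow(x$values), "values,", nrow(x$annotations), "annotations\n")
  if (!is.na(x$call_feature)) cat("  call feature:", x$call_feature, "\n")
  invisible(x)
}

#' @export
tidy.dataset_model <- function(x, ...) {
  left_join(x$values, x$features, by = c(feature = "name"))
}

#' @export
glance.dataset_model <- function(x, ...) {
  tibble(dataset_iri = x$dataset_iri, n_compounds = nrow(x$compounds),
         n_features = nrow(x$features), n_values = nrow(x$values),
         n_annotations = nrow(x$annotations))
}

#' Annotate a dataset feature with an ontology term
#'
#' Attaches a semantic link from a feature to a class in a reference
#' vocabulary: `same_as` (an `owl:sameAs` equivalence, assigned manually by
#' a curator) or `has_type` (`rdf:type`). Idempotent for an identical
#' (target, kind) pair.
#'
#' @param model A `dataset_model`.
#' @param feature_name Name of an existing feature.
#' @param target_iri IRI of the ontology term.
#' @param link_kind `"same_as"` or `"has_type"`.
#' @return The updated model.
#' @examples
#' ds <- build_dataset(read_sdf(toxowl_example("cpdbas-toy.sdf")),
#'                     "http://example.org/dataset/cpdbas-toy")
#' annotate_feature(ds, "ActivityOutcome",
#'                  "http://example.org/toxowl/endpoint#Carcinogenicity",
#'                  "same_as")
#' @export
annotate_feature <- function(model, feature_name, target_iri,
                             link_kind = c("same_as", "has_type")) {
  stopifnot(inherits(model, "dataset_model"))
  link_kind <- match.arg(link_kind)
  if (!feature_name %in% model$features$name) {
    stop_toxowl(paste0("unknown feature '", feature_name, "'"),
                "toxowl_error")
  }
  dup <- model$annotations$feature == feature_name &
    model$annotations$link_kind == link_kind &
    model$annotations$target == target_iri
  if (any(dup)) return(model)
  model$annotations <- add_row(model$annotations, feature = feature_name,
                               link_kind = link_kind, target = target_iri)
  model
}

#' The shipped default harmonization map
#'
#' Bridges the two carcinogenicity call encodings the toolchain was built
#' around: the `ActivityOutcome` field with allowed values
#' `active`/`unspecified`/`inactive`, and the numeric `Canc` field with
#' values `3` (carcinogen), `2` (equivocal), `1` (non-carcinogen). Both map
#' onto the harmonized calls `POSITIVE`/`EQUIVOCAL`/`NEGATIVE`; aligning
#' `unspecified` with `equivocal` is a mapping choice, editable in the map
#' file.
#'
#' @return A tibble with columns `feature`, `raw`, `call`.
#' @export
default_harmonization_map <- function() {
  tibble(
    feature = c(rep("ActivityOutcome", 3), rep("Canc", 3)),
    raw = c("active", "unspecified", "inactive", "3", "2", "1"),
    call = rep(c("POSITIVE", "EQUIVOCAL", "NEGATIVE"), 2))
}

#' Read a harmonization map from a YAML file
#'
#' The file maps feature names to `raw value: CALL` tables; calls must be
#' `POSITIVE`, `EQUIVOCAL` or `NEGATIVE`.
#'
#' @param path Path to the YAML map file.
#' @return A tibble with columns `feature`, `raw`, `call`.
#' @examples
#' read_harmonization_map(toxowl_example("default.map.yaml"))
#' @export
read_harmonization_map <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_toxowl(paste0("cannot read harmonization map: ",
                       conditionMessage(e)), "toxowl_rule_error",
                parent = e)
  })
  map_df <- bind_rows(imap(cfg, function(entries, feat) {
    tibble(feature = feat, raw = as.character(names(entries)),
           call = toupper(as.character(unlist(entries))))
  }))
  bad <- setdiff(unique(map_df$call),
                 c("POSITIVE", "EQUIVOCAL", "NEGATIVE"))
  if (length(bad) > 0) {
    stop_toxowl(paste0("harmonization map contains unknown call(s): ",
                       paste(bad, collapse = ", ")), "toxowl_rule_error")
  }
  map_df
}

#' Harmonize a raw carcinogenicity call
#'
#' Looks up the harmonized call for a (feature, raw value) pair; a pair the
#' map does not cover is an `toxowl_unmapped_value` error naming the
#' feature and value, never a silent guess.
#'
#' @param feature_name Feature name(s).
#' @param raw_value Raw value string(s); recycled against `feature_name`.
#' @param map A harmonization map tibble; defaults to
#'   [default_harmonization_map()].
#' @return Character vector of calls (`POSITIVE`/`EQUIVOCAL`/`NEGATIVE`).
#' @examples
#' harmonize_call("Canc", "3")
#' harmonize_call("ActivityOutcome", c("active", "inactive"))
#' @export
harmonize_call <- function(feature_name, raw_value,
                           map = default_harmonization_map()) {
  n <- max(length(feature_name), length(raw_value))
  feature_name <- rep_len(feature_name, n)
  raw_value <- rep_len(raw_value, n)
  key <- paste0(feature_name, "\r", trimws(raw_value))
  map_key <- paste0(map$feature, "\r", map$raw)
  idx <- match(key, map_key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[[1]]
    stop_toxowl(paste0("no harmonized call for feature '",
                       feature_name[[miss]], "' value '",
                       raw_value[[miss]], "'"), "toxowl_unmapped_value",
                feature = feature_name[[miss]], value = raw_value[[miss]])
  }
  map$call[idx]
}

#' Harmonized calls of a dataset's registered call feature
#'
#' @param model A `dataset_model` built with a `call_feature`.
#' @param map A harmonization map tibble.
#' @return A tibble `identifier`, `raw`, `call`, in record order.
#' @export
harmonized_calls <- function(model, map = default_harmonization_map()) {
  stopifnot(inherits(model, "dataset_model"))
  if (is.na(model$call_feature)) {
    stop_toxowl(paste0("dataset ", model$dataset_iri,
                       " has no registered call feature"), "toxowl_error")
  }
  vals <- filter(model$values, .data$feature == model$call_feature)
  tibble(identifier = vals$identifier, raw = vals$value,
         call = harmonize_call(model$call_feature, vals$value, map))
}

#' Query merged datasets for a harmonized call
#'
#' The interoperability payoff: datasets whose carcinogenicity calls are
#' encoded differently become jointly queryable once each registers its
#' call feature and the map bridges the encodings.
#'
#' @param datasets A list of `dataset_model`s, each with a registered call
#'   feature.
#' @param map A harmonization map tibble.
#' @param call The harmonized call to select
#'   (`POSITIVE`/`EQUIVOCAL`/`NEGATIVE`).
#' @return Character vector of compound identifiers across all datasets, in
#'   dataset then record order.
#' @examples
#' cp <- build_dataset(read_sdf(toxowl_example("cpdbas-toy.sdf")),
#'                     "http://example.org/dataset/cpdbas-toy",
#'                     call_feature = "ActivityOutcome")
#' is <- build_dataset(read_sdf(toxowl_example("isscan-toy.sdf")),
#'                     "http://example.org/dataset/isscan-toy",
#'                     call_feature = "Canc")
#' query_merged(list(cp, is), call = "POSITIVE")
#' @export
query_merged <- function(datasets, map = default_harmonization_map(),
                         call = c("POSITIVE", "EQUIVOCAL", "NEGATIVE")) {
  call <- match.arg(call)
  stopifnot(is.list(datasets))
  out <- character(0)
  for (ds in datasets) {
    calls <- harmonized_calls(ds, map)
    out <- c(out, calls$identifier[calls$call == call])
  }
  out
}

#' Plot harmonized call composition across datasets
#'
#' @param datasets A list of `dataset_model`s with registered call features.
#' @param map A harmonization map tibble.
#' @return A ggplot bar chart of call counts per dataset.
#' @importFrom ggplot2 geom_bar facet_wrap
#' @export
plot_harmonized_calls <- function(datasets,
                                  map = default_harmonization_map()) {
  df <- bind_rows(map(datasets, function(ds) {
    mutate(harmonized_calls(ds, map),
           dataset = local_part(ds$dataset_iri))
  }))
  ggplot(df, aes(x = .data$call)) +
    geom_bar() +
    facet_wrap(~ dataset) +
    labs(x = "harmonized call", y = "compounds",
         title = "Harmonized carcinogenicity calls")
}

# --- RDF -------------------------------------------------------------------

dataset_to_triples <- function(model) {
  ds <- model$dataset_iri
  tr <- list()
  push <- function(s, p, o) tr[[length(tr) + 1L]] <<- list(s = s, p = p, o = o)
  rdf_type <- paste0(NS_RDF, "type")

  push(ds, rdf_type, t_iri(ot("Dataset")))
  feat_iri <- stats::setNames(model$features$iri, model$features$name)
  for (i in seq_len(nrow(model$features))) {
    fi <- model$features$iri[[i]]
    push(fi, rdf_type, t_iri(ot("Feature")))
    push(fi, paste0(NS_DC, "title"), t_lit(model$features$name[[i]]))
  }
  for (i in seq_len(nrow(model$annotations))) {
    a <- model$annotations[i, ]
    p <- if (a$link_kind == "same_as") paste0(NS_OWL, "sameAs") else rdf_type
    push(feat_iri[[a$feature]], p, t_iri(a$target))
  }
  enc <- function(x) utils::URLencode(x, reserved = TRUE)
  for (i in seq_len(nrow(model$compounds))) {
    id <- model$compounds$identifier[[i]]
    ci <- paste0(ds, "/compound/", enc(id))
    ei <- paste0(ds, "/entry/", enc(id))
    push(ci, rdf_type, t_iri(ot("Compound")))
    push(ci, paste0(NS_DC, "title"), t_lit(id))
    push(ci, ot("molfile"), t_lit(model$compounds$structure_block[[i]]))
    push(ei, rdf_type, t_iri(ot("DataEntry")))
    push(ei, ot("compound"), t_iri(ci))
    push(ds, ot("dataEntry"), t_iri(ei))
    vals <- model$values[model$values$identifier == id, ]
    for (j in seq_len(nrow(vals))) {
      vi <- paste0(ds, "/value/", enc(id), "/", enc(vals$feature[[j]]))
      push(vi, rdf_type, t_iri(ot("FeatureValue")))
      push(vi, ot("feature"), t_iri(feat_iri[[vals$feature[[j]]]]))
      push(vi, ot("value"), t_lit(vals$value[[j]]))
      push(ei, ot("values"), t_iri(vi))
    }
  }
  tr
}

#' Serialize a dataset model to RDF
#'
#' Canonical Turtle (the `"n3"` format writes the same text: the package's
#' N3 output is its Turtle subset). The layout is the package's documented
#' dialect of the OpenTox model: the dataset is an `ot:Dataset` whose
#' `ot:dataEntry`s link an `ot:Compound` (with `dc:title` identifier and
#' verbatim `ot:molfile` block) to `ot:FeatureValue`s carrying the raw
#' field strings, features are `ot:Feature`s titled by field name, and
#' feature annotations appear as `owl:sameAs` or `rdf:type` links.
#'
#' @param model A `dataset_model`.
#' @param format `"turtle"` or `"n3"`.
#' @return The serialized document as a single string.
#' @export
emit_dataset_rdf <- function(model, format = c("turtle", "n3")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "dataset_model"))
  prefixes <- c("ot:" = NS_OT, "dc:" = NS_DC, "owl:" = NS_OWL,
                "rdf:" = NS_RDF, "rdfs:" = NS_RDFS, "xsd:" = NS_XSD)
  rdf_write_turtle(dataset_to_triples(model), prefixes,
                   first = model$dataset_iri)
}

#' Read a dataset model back from RDF
#'
#' Inverse of [emit_dataset_rdf()] on the package dialect. The runtime-only
#' call-feature registration is not serialized; re-register it after
#' parsing if needed.
#'
#' @param text Serialized RDF text.
#' @param format `"turtle"` or `"n3"`.
#' @return A `dataset_model`.
#' @export
parse_dataset_rdf <- function(text, format = c("turtle", "n3")) {
  format <- match.arg(format)
  tr <- parse_turtle_triples(text)
  rdf_type <- paste0(NS_RDF, "type")
  typed <- function(t) unique(tr$s[tr$p == rdf_type & tr$o == ot(t)])
  lit_of <- function(s, p) {
    v <- tr$o[tr$s == s & tr$p == p & tr$o_is_literal]
    if (length(v)) v[[1]] else NA_character_
  }
  obj_of <- function(s, p) tr$o[tr$s == s & tr$p == p & !tr$o_is_literal]

  ds_subjects <- typed("Dataset")
  if (length(ds_subjects) != 1) {
    stop_toxowl("expected exactly one ot:Dataset subject",
                "toxowl_parse_error")
  }
  ds <- ds_subjects[[1]]

  feats <- sort(typed("Feature"))
  features <- tibble(name = vapply(feats, lit_of, character(1),
                                   p = paste0(NS_DC, "title"),
                                   USE.NAMES = FALSE),
                     iri = feats)
  feat_name <- stats::setNames(features$name, features$iri)

  annotations <- list()
  for (fi in feats) {
    for (tgt in obj_of(fi, paste0(NS_OWL, "sameAs"))) {
      annotations[[length(annotations) + 1L]] <-
        tibble(feature = feat_name[[fi]], link_kind = "same_as",
               target = tgt)
    }
    for (tgt in setdiff(obj_of(fi, rdf_type), ot("Feature"))) {
      annotations[[length(annotations) + 1L]] <-
        tibble(feature = feat_name[[fi]], link_kind = "has_type",
               target = tgt)
    }
  }
  annotations <- if (length(annotations)) bind_rows(annotations)
                 else tibble(feature = character(0),
                             link_kind = character(0),
                             target = character(0))

  comp_subjects <- sort(typed("Compound"))
  compounds <- tibble(
    identifier = vapply(comp_subjects, lit_of, character(1),
                        p = paste0(NS_DC, "title"), USE.NAMES = FALSE),
    structure_block = vapply(comp_subjects, lit_of, character(1),
                             p = ot("molfile"), USE.NAMES = FALSE))
  comp_id <- stats::setNames(compounds$identifier, comp_subjects)

  values <- list()
  for (ei in sort(typed("DataEntry"))) {
    ci <- obj_of(ei, ot("compound"))
    if (length(ci) != 1) {
      stop_toxowl(paste0("data entry ", ei, " without a compound link"),
                  "toxowl_parse_error")
    }
    for (vi in sort(obj_of(ei, ot("values")))) {
      fi <- obj_of(vi, ot("feature"))
      values[[length(values) + 1L]] <-
        tibble(identifier = comp_id[[ci[[1]]]],
               feature = feat_name[[fi[[1]]]],
               value = lit_of(vi, ot("value")))
    }
  }
  values <- if (length(values)) bind_rows(values)
            else tibble(identifier = character(0), feature = character(0),
                        value = character(0))

  structure(
    list(dataset_iri = ds, compounds = compounds, features = features,
         annotations = annotations, values = values,
         call_feature = NA_character_),
    class = "dataset_model")
}

#' Test two dataset models for equal information content
#'
#' Compares dataset IRI, compound records, feature set, annotations and
#' values, ignoring row order and the runtime-only call-feature
#' registration.
#'
#' @param a,b `dataset_model` objects.
#' @return `TRUE` or `FALSE`.
#' @export
dataset_equal <- function(a, b) {
  srt <- function(df) {
    df <- as_tibble(df)
    arrange(df, !!!rlang::syms(names(df)))
  }
  identical(a$dataset_iri, b$dataset_iri) &&
    identical(srt(a$compounds), srt(b$compounds)) &&
    identical(srt(a$features), srt(b$features)) &&
    identical(srt(a$annotations), srt(b$annotations)) &&
    identical(srt(a$values), srt(b$values))
}

#' Generate a random toy SDF document
#'
#' Seeded generator emulating the two carcinogenicity dialects: records
#' carry either an `ActivityOutcome` field (values `active`, `unspecified`,
#' `inactive`) or a numeric `Canc` field (values `1`, `2`, `3`), plus a
#' `CASRN`-style auxiliary field. Molblocks are minimal single-atom V2000
#' blocks.
#'
#' @param n Number of records.
#' @param dialect `"cpdbas"` (ActivityOutcome) or `"isscan"` (Canc).
#' @param seed Integer seed.
#' @return A single string of SDF text, with attribute `records`: a tibble
#'   (`identifier`, `feature`, `value`) of the planted call fields.
#' @export
random_sdf <- function(n, dialect = c("cpdbas", "isscan"), seed) {
  dialect <- match.arg(dialect)
  with_seed(seed, {
    feature <- if (dialect == "cpdbas") "ActivityOutcome" else "Canc"
    pool <- if (dialect == "cpdbas") c("active", "unspecified", "inactive")
            else c("1", "2", "3")
    vals <- if (n > 0) sample(pool, n, replace = TRUE) else character(0)
    ids <- sprintf("%s-%03d", dialect, seq_len(n))
    blocks <- vapply(seq_len(n), function(i) {
      atom <- sample(c("C", "N", "O", "S"), 1)
      paste(
        c(ids[[i]],
          "  toxowl",
          "",
          "  1  0  0  0  0  0  0  0  0  0999 V2000",
          sprintf("    0.0000    0.0000    0.0000 %s   0  0  0  0  0  0  0  0  0  0  0  0",
                  atom),
          "M  END",
          paste0("> <", feature, ">"),
          vals[[i]],
          "",
          paste0("> <CASRN>"),
          sprintf("%d-%02d-%d", sample(10:99, 1), sample(10:99, 1),
                  sample(0:9, 1)),
          "",
          "$$$$"),
        collapse = "\n")
    }, character(1))
    structure(paste0(paste(blocks, collapse = "\n"), "\n"),
              records = tibble(identifier = ids,
                               feature = rep(feature, n), value = vals))
  })
}
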