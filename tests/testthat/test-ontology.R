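test_that("structural checks find planted violations, one edit at a time", {
  base <- random_ontology(101)$model
  expect_no_issues(base)

  mutations <- list(
    dangling_range = function(m) {
      m$object_properties <- tibble::add_row(
        m$object_properties, label = "hasGhost",
        domain = list("Class01"), range = list("Ghost"),
        comment = NA_character_)
      m
    },
    dangling_domain = function(m) {
      m$object_properties <- tibble::add_row(
        m$object_properties, label = "hasGhost2",
        domain = list("Ghost"), range = list("Class01"),
        comment = NA_character_)
      m
    },
    dangling_subclass = function(m) {
      m$subclass_axioms <- tibble::add_row(m$subclass_axioms,
                                           child = "Ghost",
                                           parent = "Class01")
      m
    },
    subclass_cycle = function(m) {
      m$subclass_axioms <- tibble::add_row(
        m$subclass_axioms,
        child = c("Class01", "Class02"), parent = c("Class02", "Class01"))
      m
    },
    duplicate_class = function(m) {
      m$classes <- tibble::add_row(m$classes, label = "Class01",
                                   comment = NA_character_)
      m
    },
    duplicate_property = function(m) {
      m$datatype_properties <- tibble::add_row(
        m$datatype_properties,
        label = rep("hasDup", 2), domain = list("Class01", "Class02"),
        datatype = rep("string", 2), comment = rep(NA_character_, 2))
      m
    })
  for (rule in names(mutations)) {
    issues <- check_structure(mutations[[rule]](base))
    expect_gt(nrow(issues), 0)
    expect_true(rule %in% issues$rule,
                info = paste("expected rule", rule, "got",
                             paste(issues$rule, collapse = ",")))
  }

  # a two-class cycle names both members
  cyc <- check_structure(mutations$subclass_cycle(base))
  expect_match(cyc$detail[cyc$rule == "subclass_cycle"][[1]], "Class01")
  expect_match(cyc$detail[cyc$rule == "subclass_cycle"][[1]], "Class02")
})

test_that("emission refuses structurally invalid models", {
  m <- ontology_model() |> add_class("A")
  m$subclass_axioms <- tibble::add_row(m$subclass_axioms,
                                       child = "A", parent = "Missing")
  expect_error(emit_owl(m, "turtle"), class = "toxowl_invalid_model")
})

test_that("ontology stats match generator bookkeeping", {
  for (seed in c(5, 77, 301)) {
    ro <- random_ontology(seed)
    s <- ontology_stats(ro$model)
    expect_identical(s$n_classes, ro$tally$n_classes)
    expect_identical(s$n_object_properties, ro$tally$n_op)
    expect_identical(s$n_datatype_properties, ro$tally$n_dp)
    expect_identical(s$n_subclass_axioms, ro$tally$n_subclass)
    expect_identical(sum(s$subclass_counts), s$n_subclass_axioms)
  }
  s0 <- ontology_stats(ontology_model())
  expect_identical(s0$n_classes, 0L)
  expect_identical(s0$n_subclass_axioms, 0L)
})

test_that("serialization is canonical and byte-stable across insertion order", {
  m1 <- ontology_model("http://example.org/o") |>
    add_class("B") |> add_class("A") |>
    add_object_property("hasB", "A", "B") |>
    add_subclass("B", "A")
  m2 <- ontology_model("http://example.org/o") |>
    add_class("A") |> add_class("B") |>
    add_subclass("B", "A") |>
    add_object_property("hasB", "A", "B")
  for (fmt in c("turtle", "rdf-xml")) {
    expect_identical(emit_owl(m1, fmt), emit_owl(m2, fmt))
    expect_identical(emit_owl(m1, fmt), emit_owl(m1, fmt))
  }
})

test_that("emit/parse round-trips preserve the model in both formats", {
  # empty model: header-only document still round-trips
  empty <- ontology_model()
  expect_true(ontology_equal(empty, parse_owl(emit_owl(empty, "turtle"),
                                              "turtle")))
  for (seed in c(2, 13, 44, 91, 150)) {
    m <- random_ontology(seed)$model
    expect_true(ontology_equal(m, parse_owl(emit_owl(m, "turtle"),
                                            "turtle")))
    expect_true(ontology_equal(m, parse_owl(emit_owl(m, "rdf-xml"),
                                            "rdf-xml")))
    # cross-format: both serializations carry the same graph
    expect_identical(nrow(rdf_triples(emit_owl(m, "turtle"), "turtle")),
                     nrow(rdf_triples(emit_owl(m, "rdf-xml"), "rdf-xml")))
  }
})

test_that("union domains serialize as class unions and parse back as sets", {
  m <- ontology_model() |>
    add_class("A") |> add_class("B") |> add_class("C") |>
    add_object_property("hasC", c("A", "B"), "C")
  ttl <- emit_owl(m, "turtle")
  expect_match(ttl, "owl:unionOf \\( :A :B \\)")
  back <- parse_owl(ttl, "turtle")
  expect_identical(back$object_properties$domain[[1]], c("A", "B"))
  # the named union expression is not mistaken for a model class
  expect_setequal(back$classes$label, c("A", "B", "C"))
})

test_that("an independent RDF parser agrees with the emitted graphs", {
  m <- convert_schema(mini_graph())$ontology
  ttl_file <- withr::local_tempfile(fileext = ".ttl")
  owl_file <- withr::local_tempfile(fileext = ".owl")
  writeLines(emit_owl(m, "turtle"), ttl_file, sep = "")
  writeLines(emit_owl(m, "rdf-xml"), owl_file, sep = "")
  script <- paste0(
    "import rdflib\n",
    "from rdflib.compare import isomorphic\n",
    "g = rdflib.Graph(); g.parse('", ttl_file, "', format='turtle')\n",
    "h = rdflib.Graph(); h.parse('", owl_file, "', format='xml')\n",
    "print(len(g), len(h), isomorphic(g, h))\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out[[length(out)]], " ")[[1]]
  own <- nrow(rdf_triples(emit_owl(m, "turtle"), "turtle"))
  expect_identical(as.integer(parts[[1]]), own)
  expect_identical(as.integer(parts[[2]]), own)
  expect_identical(parts[[3]], "True")
})

test_that("tidy and glance views expose the model as tables", {
  m <- random_ontology(8)$model
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  s <- ontology_stats(m)
  expect_identical(sum(td$kind == "class"), s$n_classes)
  expect_identical(sum(td$kind == "object_property"),
                   s$n_object_properties)
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_classes, s$n_classes)
})
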