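test_that("object property names derive from the nested child label", {
  expect_identical(derive_object_property_name("Study", "Background"),
                   "hasBackground")
  expect_identical(derive_object_property_name("Study", "ReferenceCompound"),
                   "hasReferenceCompound")
  expect_identical(derive_object_property_name("X", "X"), "hasX")
  expect_identical(derive_object_property_name("Animal", "body weight"),
                   "hasBodyWeight")
})

test_that("classify_fields partitions fields by their conversion role", {
  rep <- classify_fields(mini_graph(), default_ruleset())
  f <- schema_fields(mini_graph())
  expect_identical(nrow(rep), nrow(f))
  expect_identical(anyDuplicated(rep$path), 0L)
  d <- setNames(rep$disposition, rep$path)
  expect_identical(d[["Study"]], "class")
  expect_identical(d[["Study/Background/ReferenceCompound/Name"]],
                   "datatype_property")
  expect_identical(d[["Study/Tests/Test/Animal/Sex"]], "promoted_class")
  expect_identical(d[["Study/Tests"]], "elided_container")
  expect_identical(d[["ChronicStudies/Compounds"]], "elided_container")

  # a graph with only one complex-free root gets a single disposition row
  g1 <- parse_schema(paste0(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">',
    '<xs:element name="Solo" type="xs:string"/></xs:schema>'))
  rep1 <- classify_fields(g1, ruleset())
  expect_identical(nrow(rep1), 1L)
})

test_that("promoting a complex field is a rule conflict", {
  expect_error(
    classify_fields(mini_graph(),
                    ruleset(promotions = "Study/Background")),
    class = "toxowl_rule_error")
  expect_error(
    convert_schema(mini_graph(),
                   ruleset(renames = c("No/Such/Path" = "X"))),
    class = "toxowl_rule_error")
})

test_that("the bundled study schema converts to the expected ontology", {
  conv <- convert_schema(mini_graph(), default_ruleset())
  m <- conv$ontology
  expect_no_issues(m)

  expect_true(all(c("Study", "Background", "ReferenceCompound")
                  %in% m$classes$label))
  op <- m$object_properties
  hb <- op[op$label == "hasBackground", ]
  expect_identical(hb$domain[[1]], "Study")
  expect_identical(hb$range[[1]], "Background")
  hrc <- op[op$label == "hasReferenceCompound", ]
  expect_identical(hrc$domain[[1]], "Background")
  expect_identical(hrc$range[[1]], "ReferenceCompound")

  # containers elided: children re-attach to the container's parent
  expect_false("Tests" %in% m$classes$label)
  expect_identical(op$domain[op$label == "hasTest"][[1]], "Study")
  expect_false("Compounds" %in% m$classes$label)
  expect_identical(op$domain[op$label == "hasCompound"][[1]],
                   "ChronicStudies")

  # enumeration-driven promotion: Sex is a class reached via hasSex
  expect_true("Sex" %in% m$classes$label)
  expect_identical(op$range[op$label == "hasSex"][[1]], "Sex")

  # string leaves become datatype properties; shared names merge with
  # union domains
  dp <- m$datatype_properties
  expect_identical(dp$domain[dp$label == "hasName"][[1]],
                   c("Compound", "ReferenceCompound"))
  expect_identical(dp$datatype[dp$label == "hasNumberOfAnimals"], "integer")

  # the asserted IS-A link is the only one
  expect_identical(m$subclass_axioms,
                   tibble::tibble(child = "ChronicStudies",
                                  parent = "Study"))

  # rename applied: no Results class at the treatment-group path
  rep <- conv$report
  expect_identical(rep$label[rep$path == "Study/TreatmentGroup/Results"],
                   "TreatmentResults")
  expect_true("TreatmentResults" %in% m$classes$label)
  expect_true("Results" %in% m$classes$label)  # per-test Results remains
  expect_identical(nrow(rep), nrow(schema_fields(mini_graph())))
})

test_that("a class nested under several parents gets one union-domain property", {
  g <- parse_schema(union_schema_xsd())
  conv <- convert_schema(
    g, ruleset(containers = "Tests",
               promotions = c("ChronicStudy/Tests/Test",
                              "AcuteStudy/Tests/Test")))
  m <- conv$ontology
  expect_false("Tests" %in% m$classes$label)
  expect_identical(sum(m$classes$label == "Test"), 1L)
  op <- m$object_properties
  expect_identical(sum(op$label == "hasTest"), 1L)
  expect_identical(op$domain[op$label == "hasTest"][[1]],
                   c("AcuteStudy", "ChronicStudy"))
  expect_identical(op$range[op$label == "hasTest"][[1]], "Test")
})

test_that("renames that collide with a distinct original name are errors", {
  # renaming per-test Results to TreatmentGroup collides with the existing
  # TreatmentGroup record
  expect_error(
    convert_schema(mini_graph(),
                   ruleset(renames = c("Study/Tests/Test/Results" =
                                         "TreatmentGroup"))),
    class = "toxowl_collision_error")
  # but an explicit unification of both originals is allowed
  g <- parse_schema(paste0(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">',
    '<xs:element name="A"><xs:complexType><xs:sequence>',
    '<xs:element name="Outcome"><xs:complexType><xs:sequence>',
    '<xs:element name="V" type="xs:string"/>',
    '</xs:sequence></xs:complexType></xs:element>',
    '<xs:element name="Result"><xs:complexType><xs:sequence>',
    '<xs:element name="W" type="xs:string"/>',
    '</xs:sequence></xs:complexType></xs:element>',
    '</xs:sequence></xs:complexType></xs:element></xs:schema>'))
  conv <- convert_schema(g, ruleset(unify = c(Outcome = "Finding",
                                              Result = "Finding")))
  expect_identical(sum(conv$ontology$classes$label == "Finding"), 1L)
})

test_that("dangling subclass assertions are rejected", {
  expect_error(
    convert_schema(mini_graph(),
                   ruleset(subclasses = list(c("Ghost", "Study")))),
    class = "toxowl_rule_error")
})

test_that("conversion is deterministic and idempotent under unification", {
  g <- mini_graph()
  c1 <- convert_schema(g, default_ruleset())
  c2 <- convert_schema(g, default_ruleset())
  expect_true(ontology_equal(c1$ontology, c2$ontology))
  expect_identical(c1$report, c2$report)

  # applying convert to an already-unified schema changes nothing: a unify
  # rule whose raw labels never occur is a no-op
  c3 <- convert_schema(g, ruleset(
    containers = c("Tests", "Compounds"),
    renames = c("Study/TreatmentGroup/Results" = "TreatmentResults"),
    subclasses = list(c("ChronicStudies", "Study")),
    unify = c(TreatmentResults = "TreatmentResults")))
  expect_true(ontology_equal(c1$ontology, c3$ontology))
})

test_that("rulesets validate and load from YAML", {
  expect_error(ruleset(renames = c(a = "X", b = "X")),
               class = "toxowl_rule_error")
  rs <- read_ruleset(toxowl_example("default.rules.yaml"))
  expect_setequal(rs$containers, c("Tests", "Compounds"))
  expect_identical(rs$renames[["Study/TreatmentGroup/Results"]],
                   "TreatmentResults")
  expect_identical(rs$subclasses$child, "ChronicStudies")
  conv_file <- convert_schema(mini_graph(), rs)
  conv_def <- convert_schema(mini_graph(), default_ruleset())
  expect_true(ontology_equal(conv_file$ontology, conv_def$ontology))
})
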