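# Shared fixtures, built in code.

mini_graph <- function() parse_schema(toxowl_example("toxml-mini.xsd"))

# Six-field schema where a Tests container wraps a Test record under two
# different parents; elision must merge into one Test class with a single
# hasTest property whose domain is the union of both parents.
union_schema_xsd <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">\n',
    ' <xs:element name="ChronicStudy"><xs:complexType><xs:sequence>\n',
    '  <xs:element name="Tests"><xs:complexType><xs:sequence>\n',
    '   <xs:element name="Test" type="xs:string" maxOccurs="unbounded"/>\n',
    '  </xs:sequence></xs:complexType></xs:element>\n',
    ' </xs:sequence></xs:complexType></xs:element>\n',
    ' <xs:element name="AcuteStudy"><xs:complexType><xs:sequence>\n',
    '  <xs:element name="Tests"><xs:complexType><xs:sequence>\n',
    '   <xs:element name="Test" type="xs:string" maxOccurs="unbounded"/>\n',
    '  </xs:sequence></xs:complexType></xs:element>\n',
    ' </xs:sequence></xs:complexType></xs:element>\n',
    '</xs:schema>\n')
}

# Random valid ontology model with generator-side bookkeeping of what was
# planted, for stats and round-trip oracles.
random_ontology <- function(seed, n_classes = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_classes)) n_classes <- sample(3:12, 1)
    labels <- sprintf("Class%02d", seq_len(n_classes))
    m <- ontology_model(paste0("http://example.org/rand", seed))
    for (i in seq_len(n_classes)) {
      m <- add_class(m, labels[[i]],
                     if (runif(1) < 0.3) paste("random class", i)
                     else NA_character_)
    }
    # acyclic subclass edges: child index > parent index
    n_sub <- if (n_classes > 1) sample(0:(n_classes - 1), 1) else 0L
    sub_pairs <- unique(t(replicate(max(n_sub, 1), {
      child <- sample(2:max(n_classes, 2), 1)
      parent <- sample(seq_len(child - 1), 1)
      c(labels[[child]], labels[[parent]])
    })))
    if (n_sub > 0) {
      sub_pairs <- sub_pairs[seq_len(min(n_sub, nrow(sub_pairs))), ,
                             drop = FALSE]
      m <- add_subclass(m, sub_pairs[, 1], sub_pairs[, 2])
    }
    n_op <- sample(0:5, 1)
    for (i in seq_len(n_op)) {
      m <- add_object_property(
        m, paste0("hasRel", i),
        domain = sample(labels, sample(1:min(3, n_classes), 1)),
        range = sample(labels, 1))
    }
    n_dp <- sample(0:4, 1)
    for (i in seq_len(n_dp)) {
      m <- add_datatype_property(
        m, paste0("hasVal", i),
        domain = sample(labels, sample(1:min(2, n_classes), 1)),
        datatype = sample(c("string", "integer", "decimal"), 1))
    }
    list(model = m,
         tally = list(n_classes = n_classes,
                      n_subclass = nrow(m$subclass_axioms),
                      n_op = n_op, n_dp = n_dp))
  })
}

expect_no_issues <- function(model) {
  expect_identical(nrow(check_structure(model)), 0L)
}

toy_datasets <- function() {
  list(
    cpdbas = build_dataset(
      read_sdf(toxowl_example("cpdbas-toy.sdf")),
      "http://example.org/dataset/cpdbas-toy",
      call_feature = "ActivityOutcome"),
    isscan = build_dataset(
      read_sdf(toxowl_example("isscan-toy.sdf")),
      "http://example.org/dataset/isscan-toy",
      call_feature = "Canc"))
}

write_sdf_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".sdf",
                                .local_envir = parent.frame())
  writeLines(text, path, sep = "")
  path
}
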