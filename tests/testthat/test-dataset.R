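test_that("SDF records parse with ordered fields and verbatim molblocks", {
  recs <- read_sdf(toxowl_example("cpdbas-toy.sdf"))
  expect_identical(nrow(recs), 3L)
  expect_identical(recs$identifier,
                   c("cpdbas-001", "cpdbas-002", "cpdbas-003"))
  expect_true(all(map_lgl <- vapply(recs$properties,
                                    function(p) "ActivityOutcome" %in%
                                      names(p), logical(1))))
  # order preserved, molblock untouched through M  END
  expect_identical(names(recs$properties[[1]]),
                   c("ActivityOutcome", "CASRN"))
  expect_match(recs$structure_block[[1]], "^cpdbas-001\n")
  expect_match(recs$structure_block[[1]], "M  END$")

  # empty input yields an empty record table
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), empty)
  expect_identical(nrow(read_sdf(empty)), 0L)
})

test_that("truncated or malformed SDF records are parse errors with an index", {
  truncated <- write_sdf_text(paste0(
    "mol-1\n  x\n\n  1  0  0  0\nM  END\n> <F>\nv\n\n$$$$\n",
    "mol-2\n  x\n\n  1  0  0  0\nM  END\n> <F>\nv\n"))
  err <- tryCatch(read_sdf(truncated), error = identity)
  expect_s3_class(err, "toxowl_parse_error")
  expect_match(conditionMessage(err), "record 2")

  dup_field <- write_sdf_text(
    "mol-1\n  x\n\n  1  0  0  0\nM  END\n> <F>\nv\n\n> <F>\nw\n\n$$$$\n")
  expect_error(read_sdf(dup_field), class = "toxowl_parse_error")
})

test_that("generated SDF documents read back to the planted records", {
  for (seed in c(9, 33)) {
    n <- 4 + seed %% 5
    text <- random_sdf(n, "isscan", seed = seed)
    planted <- attr(text, "records")
    recs <- read_sdf(write_sdf_text(text))
    expect_identical(nrow(recs), as.integer(n))
    expect_identical(recs$identifier, planted$identifier)
    got <- vapply(recs$properties, function(p) p[["Canc"]], character(1))
    expect_identical(unname(got), planted$value)
  }
  # identifier can come from a named field instead of the title line
  recs <- read_sdf(toxowl_example("cpdbas-toy.sdf"), id_field = "CASRN")
  expect_identical(recs$identifier[[1]], "50-00-0")
})

test_that("datasets build one feature per distinct field", {
  recs <- read_sdf(toxowl_example("cpdbas-toy.sdf"))
  ds <- build_dataset(recs, "http://example.org/dataset/t")
  expect_setequal(ds$features$name, c("ActivityOutcome", "CASRN"))
  expect_identical(nrow(ds$values), 6L)  # 3 compounds x 2 fields

  # brute-force oracle: feature set equals the union of property keys
  text <- random_sdf(9, "cpdbas", seed = 77)
  recs2 <- read_sdf(write_sdf_text(text))
  ds2 <- build_dataset(recs2, "http://example.org/dataset/t2")
  expect_setequal(ds2$features$name,
                  unique(unlist(lapply(recs2$properties, names))))

  # empty record list: zero features
  ds0 <- build_dataset(recs[0, ], "http://example.org/dataset/none")
  expect_identical(nrow(ds0$features), 0L)
  expect_identical(nrow(ds0$values), 0L)

  # duplicate identifiers are rejected, naming the duplicates
  dup <- recs
  dup$identifier <- c("x", "x", "y")
  err <- tryCatch(build_dataset(dup, "http://example.org/d"),
                  error = identity)
  expect_s3_class(err, "toxowl_parse_error")
  expect_match(conditionMessage(err), "x")
})

test_that("feature annotation is idempotent and survives RDF round-trips", {
  ds <- toy_datasets()$cpdbas
  iri <- paste0(build_endpoint_ontology()$base_iri, "#Carcinogenicity")
  a1 <- annotate_feature(ds, "ActivityOutcome", iri, "same_as")
  expect_identical(a1, annotate_feature(a1, "ActivityOutcome", iri,
                                        "same_as"))
  expect_error(annotate_feature(ds, "NoSuchFeature", iri, "same_as"),
               class = "toxowl_error")

  a2 <- annotate_feature(a1, "CASRN", iri, "has_type")
  for (fmt in c("turtle", "n3")) {
    back <- parse_dataset_rdf(emit_dataset_rdf(a2, fmt), fmt)
    expect_true(dataset_equal(a2, back))
    expect_true("same_as" %in% back$annotations$link_kind)
    expect_true("has_type" %in% back$annotations$link_kind)
  }
  # the sameAs link is visible in the emitted text
  expect_match(emit_dataset_rdf(a1), "owl:sameAs", fixed = TRUE)
})

test_that("RDF round-trips hold on fuzzed datasets and the empty dataset", {
  for (seed in c(14, 52)) {
    text <- random_sdf(6, sample(c("cpdbas", "isscan"), 1), seed = seed)
    ds <- build_dataset(read_sdf(write_sdf_text(text)),
                        paste0("http://example.org/dataset/f", seed))
    expect_true(dataset_equal(ds, parse_dataset_rdf(emit_dataset_rdf(ds))))
  }
  recs0 <- read_sdf(toxowl_example("cpdbas-toy.sdf"))[0, ]
  ds0 <- build_dataset(recs0, "http://example.org/dataset/empty")
  back0 <- parse_dataset_rdf(emit_dataset_rdf(ds0))
  expect_true(dataset_equal(ds0, back0))
})

test_that("harmonized calls bridge both encodings and reject unknown values", {
  expect_identical(harmonize_call("Canc", "3"), "POSITIVE")
  expect_identical(harmonize_call("Canc", c("1", "2")),
                   c("NEGATIVE", "EQUIVOCAL"))
  expect_identical(harmonize_call("ActivityOutcome", "active"), "POSITIVE")
  expect_identical(harmonize_call("ActivityOutcome", "unspecified"),
                   "EQUIVOCAL")
  err <- tryCatch(harmonize_call("Canc", "7"), error = identity)
  expect_s3_class(err, "toxowl_unmapped_value")
  expect_match(conditionMessage(err), "Canc")
  expect_match(conditionMessage(err), "7")

  # the YAML map file equals the built-in default
  expect_identical(
    dplyr::arrange(read_harmonization_map(
      toxowl_example("default.map.yaml")), feature, raw),
    dplyr::arrange(default_harmonization_map(), feature, raw))
})

test_that("merged queries return the hand-enumerated positives", {
  ds <- toy_datasets()
  expect_identical(query_merged(ds, call = "POSITIVE"),
                   c("cpdbas-001", "cpdbas-002", "isscan-001"))
  expect_identical(query_merged(ds, call = "NEGATIVE"),
                   c("cpdbas-003", "isscan-002"))
  expect_identical(query_merged(list(), call = "POSITIVE"), character(0))
  no_cf <- build_dataset(read_sdf(toxowl_example("cpdbas-toy.sdf")),
                         "http://example.org/d")
  expect_error(query_merged(list(no_cf), call = "POSITIVE"),
               class = "toxowl_error")

  # brute-force oracle on fuzzed datasets: filter all value triples by the
  # mapped call
  for (seed in c(61, 88)) {
    d1 <- build_dataset(
      read_sdf(write_sdf_text(random_sdf(8, "cpdbas", seed = seed))),
      "http://example.org/dataset/a", call_feature = "ActivityOutcome")
    d2 <- build_dataset(
      read_sdf(write_sdf_text(random_sdf(7, "isscan", seed = seed + 1))),
      "http://example.org/dataset/b", call_feature = "Canc")
    hmap <- default_harmonization_map()
    for (call in c("POSITIVE", "EQUIVOCAL", "NEGATIVE")) {
      oracle <- character(0)
      for (d in list(d1, d2)) {
        v <- d$values[d$values$feature == d$call_feature, ]
        for (i in seq_len(nrow(v))) {
          hit <- hmap$call[hmap$feature == v$feature[[i]] &
                             hmap$raw == v$value[[i]]]
          if (identical(hit, call)) oracle <- c(oracle, v$identifier[[i]])
        }
      }
      expect_identical(query_merged(list(d1, d2), hmap, call), oracle)
    }
  }
})

test_that("the positive sets from both dialects coincide under the map", {
  # interoperability at the data-model level: each dialect's native
  # positive encoding lands on the same harmonized call
  hmap <- default_harmonization_map()
  expect_identical(harmonize_call("ActivityOutcome", "active", hmap),
                   harmonize_call("Canc", "3", hmap))
  # and the map is total over each feature's allowed values, one call each
  counts <- dplyr::count(hmap, feature, raw)
  expect_true(all(counts$n == 1))
  expect_setequal(hmap$raw[hmap$feature == "ActivityOutcome"],
                  c("active", "unspecified", "inactive"))
  expect_setequal(hmap$raw[hmap$feature == "Canc"], c("1", "2", "3"))
})
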