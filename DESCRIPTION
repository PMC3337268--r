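Package: toxowl
Title: Lift Toxicology XML Schemas into OWL Ontologies and Annotate Chemical Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based toolchain for making heterogeneous toxicology data
    semantically interoperable. Parses an XSD-style schema of nested toxicity
    study records into a field graph, applies declarative conversion rules
    (container elision, renames, promotion of enumerated strings to classes,
    explicit subclass assertions) to lift it into a flat OWL-DL ontology with
    hasX object properties between nested record types, and serializes the
    result deterministically to Turtle or RDF/XML. Ships programmatically
    built toxicological endpoint and organ-system/effects vocabularies,
    parsers for heterogeneous indicator values (survival ratios with optional
    week ranges, qualitative effect phrases), and an RDF dataset model that
    reads SDF chemical files, annotates dataset features with ontology terms,
    and harmonizes conflicting carcinogenicity call encodings across
    databases so they become jointly queryable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
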