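#' Build the toxicological endpoint vocabulary
#'
#' Programmatically constructs the endpoint ontology skeleton used to
#' annotate dataset features: `ToxicityStudyType` with its five study types
#' (carcinogenicity, in vitro bacterial mutagenicity, in vivo micronucleus
#' mutagenicity, repeated dose toxicity, aquatic toxicity), the three
#' repeated-dose variants (chronic, sub-chronic, sub-acute), `TestSystem`
#' (strain, species, sex, route of exposure) and `TestResult` (toxicity
#' measure, test call, mode of action, target site).
#'
#' @param base_iri Namespace for the vocabulary; defaults to a dedicated
#'   `/endpoint` namespace under the package default.
#' @return An `ontology_model` that passes [check_structure()].
#' @examples
#' ontology_stats(build_endpoint_ontology())
#' @export
build_endpoint_ontology <- function(base_iri = paste0(DEFAULT_BASE_IRI,
                                                      "/endpoint")) {
  m <- ontology_model(base_iri)
  m <- add_class(m, "ToxicityStudyType",
                 "A category of toxicity study an endpoint belongs to")
  study_types <- c("Carcinogenicity", "InVitroBacterialMutagenicity",
                   "InVivoMicronucleusMutagenicity", "RepeatedDoseToxicity",
                   "AquaticToxicity")
  m <- add_class(m, study_types)
  m <- add_subclass(m, study_types, rep("ToxicityStudyType",
                                        length(study_types)))

  rdt <- c("Chronic", "SubChronic", "SubAcute")
  m <- add_class(m, rdt)
  m <- add_subclass(m, rdt, rep("RepeatedDoseToxicity", length(rdt)))

  m <- add_class(m, "TestSystem",
                 "The biological system and exposure conditions of a test")
  ts <- c("Strain", "Species", "Sex", "RouteOfExposure")
  m <- add_class(m, ts)
  m <- add_subclass(m, ts, rep("TestSystem", length(ts)))

  m <- add_class(m, "TestResult", "The recorded outcome of a test")
  tr <- c("ToxicityMeasure", "TestCall", "ModeOfAction", "TargetSite")
  m <- add_class(m, tr)
  m <- add_subclass(m, tr, rep("TestResult", length(tr)))
  m
}

#' Build the organ-system and effects vocabulary
#'
#' Constructs the organ/effects ontology skeleton: an `OrganSystem` class
#' with the 13 rodent organ systems as direct subclasses, each linkable via
#' `hasAnatomicalStructure` to `AnatomicalStructure` subclasses (demo
#' content is populated for the respiratory and digestive tracts, with
#' `hasSynonym` terminology cross-links and `hasCellType` /
#' `hasHormoneOrEnzyme` object links), and an effects side where `Effect`
#' classes link to `PathologicalEffect`s which link to `DiagnosticFeature`s
#' (respiratory-tract demo content). Multi-word system names become single
#' camel-case labels; the full phrase is kept as the class comment. The
#' anatomical and effect content is an illustrative scaffold, not a full
#' histopathology nomenclature; the vocabulary focuses on organs observed
#' in rodents (species specificity is noted as an annotation, not modeled).
#'
#' @param base_iri Namespace for the vocabulary.
#' @return An `ontology_model` that passes [check_structure()].
#' @examples
#' ontology_stats(build_organs_effects_ontology())$subclass_counts[["OrganSystem"]]
#' @export
build_organs_effects_ontology <- function(base_iri = paste0(DEFAULT_BASE_IRI,
                                                            "/organs")) {
  systems <- c(
    DigestiveSystem = "digestive system",
    RespiratorySystem = "respiratory system",
    CirculatorySystem = "circulatory system",
    EndocrineSystem = "endocrine system",
    MaleGenitalSystem = "male genital system",
    FemaleGenitalSystem = "female genital system",
    HematopoieticSystem = "hematopoietic system",
    IntegumentarySystem = "integumentary system",
    BodyCavities = "body cavities",
    NervousSystemAndSpecialSenseOrgans =
      "nervous system and special sense organs",
    UrinarySystem = "urinary system",
    MusculoskeletalSystem = "musculoskeletal system",
    ImmuneSystemAndLymphaticOrgans = "immune system and lymphatic organs")

  m <- ontology_model(base_iri)
  m <- add_class(m, "OrganSystem",
                 paste("An organ system observed in rodent toxicity",
                       "studies (rodent focus; species specificity to be",
                       "layered on separately)"))
  m <- add_class(m, names(systems), unname(systems))
  m <- add_subclass(m, names(systems),
                    rep("OrganSystem", length(systems)))

  m <- add_class(m, "AnatomicalStructure",
                 "An anatomical structure belonging to an organ system")
  m <- add_object_property(m, "hasAnatomicalStructure",
                           domain = "OrganSystem",
                           range = "AnatomicalStructure")
  m <- add_datatype_property(m, "hasSynonym", "AnatomicalStructure",
                             "string",
                             comment = "Terminology cross-link")
  m <- add_class(m, "CellType",
                 "A main cell type of an organ tissue")
  m <- add_object_property(m, "hasCellType", "AnatomicalStructure",
                           "CellType")
  m <- add_class(m, "HormoneOrEnzyme",
                 "A main hormone or enzyme of an organ tissue")
  m <- add_object_property(m, "hasHormoneOrEnzyme", "AnatomicalStructure",
                           "HormoneOrEnzyme")

  # Demo anatomical content: respiratory and digestive tracts only.
  resp <- c("NasalCavity", "Larynx", "Trachea", "Bronchus", "Lung")
  dig <- c("Esophagus", "Stomach", "SmallIntestine", "LargeIntestine",
           "Liver", "Pancreas")
  m <- add_class(m, c(resp, dig))
  m <- add_subclass(m, c(resp, dig),
                    rep("AnatomicalStructure", length(c(resp, dig))))
  demo_cells <- c("ClaraCell", "TypeIIPneumocyte", "Hepatocyte")
  m <- add_class(m, demo_cells)
  m <- add_subclass(m, demo_cells, rep("CellType", length(demo_cells)))
  demo_h <- c("Surfactant", "Pepsin", "Insulin")
  m <- add_class(m, demo_h)
  m <- add_subclass(m, demo_h, rep("HormoneOrEnzyme", length(demo_h)))

  # Effects side: effects -> pathological effects -> diagnostic features.
  m <- add_class(m, "Effect",
                 "A neoplastic or non-neoplastic effect observed in vivo")
  m <- add_class(m, "PathologicalEffect",
                 "A pathological manifestation of an effect")
  m <- add_class(m, "DiagnosticFeature",
                 "A detailed diagnostic feature of a pathological effect")
  m <- add_object_property(m, "hasPathologicalEffect", "Effect",
                           "PathologicalEffect")
  m <- add_object_property(m, "hasDiagnosticFeature", "PathologicalEffect",
                           "DiagnosticFeature")

  demo_eff <- c("Inflammation", "Hyperplasia")
  m <- add_class(m, demo_eff)
  m <- add_subclass(m, demo_eff, rep("Effect", length(demo_eff)))
  demo_path <- c("BronchioloalveolarHyperplasia", "ChronicActiveInflammation")
  m <- add_class(m, demo_path)
  m <- add_subclass(m, demo_path,
                    rep("PathologicalEffect", length(demo_path)))
  demo_diag <- c("IncreasedCellularity", "InflammatoryCellInfiltrate")
  m <- add_class(m, demo_diag)
  m <- add_subclass(m, demo_diag,
                    rep("DiagnosticFeature", length(demo_diag)))
  m
}

#' Write the packaged vocabularies to OWL files
#'
#' Regenerates `endpoint.owl`/`.ttl` and `organs_effects.owl`/`.ttl`
#' (RDF/XML and Turtle respectively) in `dir`. Output is byte-stable: the
#' builders are deterministic and the serialization canonical.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_fixture_ontologies <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  builds <- list(endpoint = build_endpoint_ontology(),
                 organs_effects = build_organs_effects_ontology())
  paths <- character(0)
  for (nm in names(builds)) {
    owl <- file.path(dir, paste0(nm, ".owl"))
    ttl <- file.path(dir, paste0(nm, ".ttl"))
    writeLines(emit_owl(builds[[nm]], "rdf-xml"), owl, sep = "")
    writeLines(emit_owl(builds[[nm]], "turtle"), ttl, sep = "")
    paths <- c(paths, owl, ttl)
  }
  invisible(paths)
}
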