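---
title: "Lifting toxicology schemas into OWL and harmonizing carcinogenicity calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifting toxicology schemas into OWL and harmonizing carcinogenicity calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxowl)
library(dplyr)
```

## The problem

Toxicity databases describe the same biology in incompatible ways. One
database records a carcinogenicity outcome as an `ActivityOutcome` string
(`active`/`unspecified`/`inactive`); another uses a numeric `Canc` code
whose meaning (3 = carcinogen, 2 = equivocal, 1 = non-carcinogen) lives
only in a PDF guidance document. Study records exchanged as XML follow a
deeply nested schema in which semantically different record types share a
name (`Results` under a test vs. under a treatment group), wrappers such as
`Tests` or `Compounds` exist purely to frame repetition, and indicator
values mix types freely -- the same survival-rate indicator appears as
`'0/5 (weeks 27-30)'` in one chronic study and as a bare `'10/10'` in
another.

toxowl makes such data jointly processable by machines: it lifts a nested
XML schema into a flat OWL-DL ontology under explicit expert rules,
provides typed parsers for the heterogeneous indicator values, ships small
endpoint and organ/effects vocabularies for annotation, and represents SDF
chemical datasets in an RDF dataset model in which feature-level ontology
links and a declarative harmonization map make differently-encoded
carcinogenicity calls queryable together.

## The conversion procedure

`parse_schema()` reads an XSD subset (elements, inline or named complex
types with sequences/choices, string restrictions with enumerations,
occurrence attributes) into a flat field table keyed by slash-joined paths.
`convert_schema()` then applies, in order:

1. **Classification.** Complex fields become classes; string/numeric
   leaves become datatype properties; enumerated or expert-listed string
   leaves are *promoted* to classes; fields matching the container rule
   are elided.
2. **Relabelling.** Path-scoped renames, then label unifications, then
   UpperCamelCase normalization.
3. **Class creation**, deduplicated by final label: the same record type
   used in many contexts becomes one class related to all of its parents.
4. **Object properties.** Every surviving nesting tuple (F1, F2) yields
   `has<F2>` with domain F1 and range F2; when F2 survives under *k*
   parents the single property's domain is the union of the *k* parent
   classes.
5. **Datatype properties** `has<X>` typed `xsd:string`/`integer`/`decimal`
   from the leaf kind.
6. **Explicit IS-A only.** The only subclass axioms emitted are the
   ruleset's assertions (e.g. `ChronicStudies` &#8834; `Study`). XML
   nesting expresses containment, not specialization, so the output is
   deliberately flat.

The conversion report accounts for every input field exactly once; the
property suite asserts this totality over seeded random schemas.

### Rule semantics that were genuinely open

* **Merge vs. collision.** Identical labels arising from the *same*
  original element name merge into one class (that is the point of
  deduplication). A collision between *originally distinct* names -- e.g.
  a rename that lands on an existing class -- is an error unless the
  ruleset unified both spellings explicitly. Declarative intent wins over
  silent merging.
* **Containers are declarative.** `Tests` and `Compounds` are elided by
  the default ruleset because wrapper elements carry no ontological
  meaning; matching is by bare name anywhere or by full path. Only complex
  fields are elided -- a leaf that happens to share a container name stays
  a property. No heuristic container detection is enabled by default:
  rules are expert statements, and an unlisted wrapper simply becomes a
  (harmless) class.
* **Promotion policy.** "Replace strings by named concepts wherever
  possible" is operationalized as *enumerated or explicitly listed*. Free
  text cannot be promoted safely; an enumeration is already a closed
  vocabulary, so `Sex {Male, Female}` becomes a class reached via
  `hasSex`, with the allowed values kept as a class comment.
* **Empty complex elements.** The field invariant ties
  `value_kind = "complex"` to having children, so an element with an empty
  complex type is recorded as a childless string leaf rather than an
  empty class.
* **Occurrence.** `minOccurs`/`maxOccurs` are recorded for reporting but
  produce no cardinality axioms; none are needed by the downstream
  consumers and none would survive the flat design.

## Serialization choices

No RDF stack exists in this package's R dependency set, and byte-stable
output is a design requirement, so serialization is implemented here and
kept deliberately small:

* **Canonical ordering.** Subjects sort by IRI (ontology header first),
  `rdf:type` leads each block, remaining predicates sort by predicate then
  object. Identical models therefore always produce identical bytes, in
  both Turtle and RDF/XML, which makes equality checks and regeneration
  diffs trivial.
* **Named unions.** A domain or range spanning several classes is written
  as `owl:unionOf` under a deterministically named expression
  (`UnionOf_<sorted members>`); apart from the RDF collection backbone of
  that construct, no blank nodes are emitted.
* **Reading.** `parse_owl()`/`parse_dataset_rdf()` invert the package's
  own dialect (triple order does not matter); they are not general
  Turtle/RDF-XML readers. The test suite additionally re-parses emitted
  files with an independent RDF library and checks triple counts and
  cross-format graph isomorphism.
* **N3.** The dataset writer's N3 output is its Turtle subset -- every
  such document is valid N3 -- so both format names drive one serializer.
* **Consistency gate.** In place of a description-logic reasoner,
  `check_structure()` enforces the structural invariants (resolvable
  domains/ranges/axioms, unique labels, acyclic subclassing). The
  ontologies produced here contain no constructs that would require
  tableau reasoning beyond these checks; that is a documented limitation,
  not an accident.

## Value normalization

`parse_ratio()` implements the grammar `INT "/" INT ["(weeks" INT "-"
INT ")"]` with flexible whitespace and a case-insensitive keyword (one
dialect of the week range is attested, so only one is accepted). Syntax
errors and domain errors are distinct conditions: `"6/5"` is well-formed
but impossible (more survivors than tested animals) and raises
`toxowl_domain_error`, not a parse error. Whether a week interval
qualifies the deaths or the measurement time is not stated in the source
records, so the record stores the interval without interpreting it. In
non-strict mode out-of-grammar values are carried verbatim with a flag --
inconsistent records are a fact of the data and must not be dropped.
`parse_effect()` splits `"MORTALITY, INCREASED"`-style strings on the last
comma and maps direction synonyms onto the closed set
`INCREASED`/`DECREASED`/`UNCHANGED`.

## The dataset model and harmonization

`read_sdf()` frames records with ChemmineR and keeps the structure block
verbatim; `build_dataset()` mints one `ot:Feature` per distinct field name
and one `ot:FeatureValue` per cell under a minimal constant slice of the
OpenTox namespace (no external vocabulary download is required).
Annotation is manual and feature-level: `owl:sameAs` for curator-asserted
equivalence, `rdf:type` for classification, both idempotent.

The harmonization map is total over each feature's allowed values and maps
each raw value to exactly one of `POSITIVE`/`EQUIVOCAL`/`NEGATIVE`.
Aligning `unspecified` with the numeric equivocal code is a mapping
choice, not a fact of either source; it lives in an editable YAML file
rather than in code. `query_merged()` then answers "all positives across
databases" directly, which is the interoperability pay-off the package
exists for.

## What the generators emulate, and what they do not

`random_schema()` emits seeded nested schemas (complex records, typed
leaves, occasional enumerations, recurring names across contexts) with
generator-side bookkeeping, sized 3--25 fields in the shipped property
suites; `random_sdf()` emits seeded SDF documents in both call dialects
with single-atom V2000 molblocks. They reproduce the *structural*
phenomena the toolchain handles -- nesting, ambiguity, mixed value types,
conflicting encodings -- but not the scale (thousands of fields and
compounds), chemistry (real connection tables), free-text noise, or
schema constructs outside the supported subset. Green property suites
therefore demonstrate correctness of the conversion and harmonization
logic under those structural conditions, not robustness to arbitrary
real-world XSD or SDF files.

Problem sizes used by the shipped suites: 200 seeded random schemas for
report totality, 30 for the union-domain brute-force comparison, 10^4
seeded draws for the ratio format/parse round-trip, and a handful of
random ontologies/datasets for serialization round-trips -- all chosen as
comfortably exhaustive for desk-scale structures.

## Worked example

```{r convert}
g <- parse_schema(toxowl_example("toxml-mini.xsd"))
ambiguous_names(g)

conv <- convert_schema(g, default_ruleset())
count(conv$report, disposition)
glance(conv)
```

```{r owl}
cat(substr(emit_owl(conv$ontology, "turtle"), 1, 600))
```

```{r harmonize}
cp <- build_dataset(read_sdf(toxowl_example("cpdbas-toy.sdf")),
                    "http://example.org/dataset/cpdbas-toy",
                    call_feature = "ActivityOutcome")
is <- build_dataset(read_sdf(toxowl_example("isscan-toy.sdf")),
                    "http://example.org/dataset/isscan-toy",
                    call_feature = "Canc")
query_merged(list(cp, is), call = "POSITIVE")
```

```{r values}
parse_ratio(readLines(toxowl_example("survival_rates.txt")))
```

## Known limitations

* The XSD subset is fixed; imports/includes, attributes, element
  references, substitution groups and mixed content are hard errors. The
  schema is assumed self-contained.
* The shipped vocabularies are scaffolds: the anatomical, cell-type and
  effect demo content illustrates the linking structure and is not a
  nomenclature reproduction; species specificity is an annotation only.
* RDF reading covers the package's canonical dialect, not arbitrary
  Turtle; structural checking is not DL reasoning.
* The default ruleset encodes only the documented rule instances; real
  schemas need their own expert ruleset, which is exactly what the
  declarative format is for.
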