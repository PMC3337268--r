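# toxowl

Semantic interoperability tooling for toxicology data, in R.

Public toxicity databases encode the same fact in incompatible ways: one
ships SDF files whose carcinogenicity outcome is an `ActivityOutcome`
string (`active`/`unspecified`/`inactive`), another a numeric `Canc` code
(3 = carcinogen, 2 = equivocal, 1 = non-carcinogen) documented only in a
separate guidance PDF. Study records exchanged as XML follow deeply nested
schemas where wrapper elements (`Tests`, `Compounds`) carry no meaning,
the same name (`Results`) labels different record types in different
contexts, and indicator values mix types freely — the same survival-rate
indicator appears as `'0/5 (weeks 27-30)'` in one chronic study and as
`'10/10'` in another.

toxowl addresses this for tool builders and data curators in predictive
toxicology:

* **Schema lifting.** `parse_schema()` + `convert_schema()` turn an
  XSD-style schema into a flat OWL-DL ontology under a declarative expert
  ruleset. For every nesting tuple (F1, F2) it emits one object property
  *has*F2 with `rdfs:domain` F1 and `rdfs:range` F2 (a union of classes
  when F2 recurs under several parents); string/numeric leaves become
  *has*X datatype properties; enumerated leaves are promoted to named
  classes; containers are elided; the only `rdfs:subClassOf` axioms are
  the ruleset's explicit assertions (e.g. `ChronicStudies ⊂ Study`). A
  conversion report accounts for 100% of the fields.
* **Deterministic OWL serialization.** `emit_owl()` writes canonical
  Turtle or RDF/XML (byte-stable across runs and insertion orders);
  `parse_owl()` reads it back; `check_structure()` validates domains,
  ranges, label uniqueness and subclass acyclicity.
* **Packaged vocabularies.** `build_endpoint_ontology()` (five toxicity
  study types under `ToxicityStudyType`, test-system and test-result
  branches) and `build_organs_effects_ontology()` (13 rodent organ
  systems, anatomical structures, effects linked to pathological effects
  and diagnostic features).
* **Value normalization.** `parse_ratio()` types survival ratios
  `n/d [(weeks a-b)]` with numerator ≤ denominator enforced as a domain
  (not syntax) error; `parse_effect()` types `"MORTALITY, INCREASED"`
  style observations.
* **Dataset annotation and harmonization.** `read_sdf()` /
  `build_dataset()` represent SDF files in the OpenTox `ot:Dataset` /
  `ot:Feature` / `ot:FeatureValue` model, `annotate_feature()` attaches
  `owl:sameAs` / `rdf:type` links to ontology terms, and
  `harmonize_call()` + `query_merged()` answer cross-database queries
  such as "all carcinogens" through a declarative harmonization map.

Everything is pipe-friendly: tabular surfaces are tibbles, fitted objects
have `tidy()`/`glance()` methods and ggplot2 `autoplot()` views, and a
CLI (`inst/cli/toxowl`) exposes the pipeline as subcommands (`convert`,
`fixtures`, `annotate`, `harmonize-query`, `parse-values`, `validate`).

## Worked example

```r
library(toxowl)
library(dplyr)

g <- parse_schema(toxowl_example("toxml-mini.xsd"))
ambiguous_names(g)
#> # A tibble: 2 × 3
#>   name    n_paths paths
#>   <chr>     <int> <list>
#> 1 Name          2 <chr [2]>
#> 2 Results       2 <chr [2]>
```

`Results` names two different record types, so the default ruleset
renames the treatment-group one to `TreatmentResults`; `Name` merges into
one datatype property with a union domain.

```r
conv <- convert_schema(g, default_ruleset())
count(conv$report, disposition)
#> # A tibble: 4 × 2
#>   disposition           n
#>   <chr>             <int>
#> 1 class                10
#> 2 datatype_property     8
#> 3 elided_container      2
#> 4 promoted_class        1

cat(emit_owl(conv$ontology, "turtle"))
#> ...
#> :ChronicStudies a owl:Class ;
#>     rdfs:label "ChronicStudies" ;
#>     rdfs:subClassOf :Study .
#> ...
#> :hasBackground a owl:ObjectProperty ;
#>     rdfs:domain :Study ;
#>     rdfs:label "hasBackground" ;
#>     rdfs:range :Background .
#> ...
```

The 21 schema fields become 11 classes (including promoted `Sex`), 9
object properties, 7 datatype properties and the single asserted subclass
axiom — a flat ontology in which `Study` relates to `Background`, which
relates to `ReferenceCompound`, while the `Tests` and `Compounds`
wrappers have disappeared.

Harmonized querying over the two bundled toy datasets (CPDBAS-style
strings, ISSCAN-style codes):

```r
cp <- build_dataset(read_sdf(toxowl_example("cpdbas-toy.sdf")),
                    "http://example.org/dataset/cpdbas-toy",
                    call_feature = "ActivityOutcome")
is <- build_dataset(read_sdf(toxowl_example("isscan-toy.sdf")),
                    "http://example.org/dataset/isscan-toy",
                    call_feature = "Canc")
query_merged(list(cp, is), call = "POSITIVE")
#> [1] "cpdbas-001" "cpdbas-002" "isscan-001"
```

Two `active` compounds and one `Canc = 3` compound land in one positive
set, which is the interoperability point of the package. And the typed
survival ratios:

```r
parse_ratio(c("0/5 (weeks 27-30)", "10/10"))
#> # A tibble: 2 × 6
#>   text              numerator denominator period_start_week period_end_week parsed
#>   <chr>                 <int>       <int>             <int>           <int> <lgl>
#> 1 0/5 (weeks 27-30)         0           5                27              30 TRUE
#> 2 10/10                    10          10                NA              NA TRUE
```

See `vignettes/lifting-toxicology-schemas.Rmd` for the full account of
the conversion rules, serialization guarantees and design choices.

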