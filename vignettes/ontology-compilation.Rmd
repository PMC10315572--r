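---
title: "Compiling a plant/pest coding system into an OWL ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling a plant/pest coding system into an OWL ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eppoforge)
```

## The problem

EPPO-style coding systems identify plants, pests and pathogens with short
5–6 character codes and ship as relational artifacts: a code table with
multilingual names, a replaced-codes history, phytosanitary categorization
lists per country or region, and host–pest relation records. `eppoforge`
compiles these sources into an OWL 2 ontology so the content can be
queried with SPARQL, linked to external taxonomies and consumed as one
harmonized knowledge graph. This vignette documents the model, the design
choices that were genuinely open, the numerical/degenerate-input behaviour,
and what the synthetic fixtures do and do not establish.

## Pipeline and model

The pipeline is ingest → assemble → validate → emit → enrich → verify:

1. **Ingest** (`parse_code_table()`, `parse_replaced_codes()`,
   `parse_categorization_list()`, `parse_host_pest_relations()`,
   `parse_scheme_config()`): the code table comes as CSV tables (`codes`,
   `names`, `links`) or an equivalent SQLite database; relations arrive as
   JSON arrays emulating REST payloads; the expert configuration
   (categorization hierarchy and q-list map, taxonomy levels, code types,
   ontology-header metadata) is one YAML file. Since the upstream database
   layout is not standardized, the canonical schema here is the minimal
   closure over every modelled field.
2. **Assemble/validate** (`assemble_kb()`, `validate_kb()`): indexes are
   built, duplicates rejected, and referential integrity checked — parents
   exist and form a forest, relation endpoints and categorization subjects
   exist (subjects taxonomic), replacements resolve without cycles.
   Unresolvable categorization q-lists are *warnings*, because classifying a
   new list is the human step of the maintenance process; `strict = TRUE`
   escalates warnings, `lenient = TRUE` downgrades a missing parent and the
   emitter attaches the orphan under its kind root.
3. **Emit** (`build_graph()`, `serialize_graph()`): codes become OWL classes
   linked by direct object-property triples (OWL 2 punning). The alternative
   — existential restrictions (`subClassOf someValuesFrom`) — was considered
   and rejected: punning matches how the ontology's own worked excerpts are
   written and keeps every competency-question query a single triple
   pattern.
4. **Enrich** (`build_taxon_index()`, `match_annotations()`,
   `apply_mappings()`): exact matching on normalized lexemes against an OBO
   lexicon, injecting `oboInOwl:hasDbXref`.
5. **Verify** (`run_builtin_suite()`, `load_cq_suite()`): competency
   questions as SPARQL with expected answers, compared under
   `set_equal` / `subset` / `boolean` modes.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `strict` | `validate_kb()` | `FALSE` | warnings mark human-review items, not build stoppers |
| `lenient` | `validate_kb()`, `build_graph()` | `FALSE` | orphan parents are usually data errors; opt in to keep going |
| `policy` | `apply_mappings()` | `"all"` | `hasDbXref` is repeatable by OBO convention; ambiguous hits stay flagged in the report rather than silently dropped; `"unambiguous_only"` suits conservative releases |
| `base_iri` | `eppo_vocabulary()` | published EPPO ontology namespace | keeps competency-question answers comparable |
| `compare` | CQ suites | `set_equal` | exact answer sets; `subset` for open-ended questions |

## Design choices on open points

- **Activity flag IRI**: the sources render the flag both as `isActive` and
  `is_active`; the camel-case `isActive` is used everywhere, treating the
  other spelling as a rendering of the same property.
- **Taxonomy-level distance baseline**: `has_taxonomy_level` is the number
  of subclass steps from the code to its kind root within the code
  hierarchy. The upstream definition leaves the baseline open; counting from
  the kind root makes the value derivable from the emitted graph alone.
- **Association direction**: `sio:SIO_001403` is asserted from the record
  that lists the association (the taxon side in the worked example), not
  duplicated in both directions; the first built-in competency question
  depends on exactly that direction.
- **Host/pest orientation**: the host bears `has_pest_type_<c>` to the pest
  and the pest bears `has_host_type_<c>` to the host; each pair is declared
  mutually inverse and subproperties of `has_pest`/`has_host`.
- **Replacement dates**: the replaced-code history carries an optional date
  that has no property in the target schema; it is preserved as a
  `dcterms:created` annotation on a reified `obo:IAO_0100001` triple, using
  the same `owl:Axiom` mechanism as name metadata, so the graph walk-back
  is lossless.
- **Name reification trigger**: a name gets an `owl:Axiom` node iff it
  carries a creation/modification date, an authority, or is inactive; the
  node then always includes the `isActive` annotation. A plain active name
  stays a single triple.
- **Categorization-status fields** (continent, country, ISO code, q-list,
  years) are plain literals on the status class — linking them to a
  locations ontology is deliberately out of scope here.
- **Code syntax**: `^[0-9A-Z]{5,6}$`. The prose definition says letters,
  but published codes such as `1TRZG` and `3SWHC` carry digits, so
  alphanumerics are admitted and lowercase/other lengths rejected.
- **Description field**: the schema's code attributes include a definition
  (`rdfs:comment`), and one competency question expects it, so code records
  carry an optional `comment`.

## Numerical and degenerate behaviour

- **Determinism**: serialization orders prefixes, subjects (IRIs before
  blank nodes), predicates (`rdf:type` first) and objects with a
  locale-independent radix sort; equal graphs give byte-identical files.
  Axiom-node labels are assigned in emission order, which is itself fixed
  by the knowledge base's canonical ordering (codes sorted by identifier,
  names by role/language/text, relations and statuses by all fields).
- **Status IRI collisions**: status IRIs are
  `code + "_CAT_" + slug(q_list) + "_" + iso`; when two statuses collide
  (same code, list and country), the year added is appended; a collision
  surviving that is an explicit minting error rather than silent overwrite.
- **Degenerate inputs**: empty bundles parse to empty collections, an empty
  KB emits a T-Box-only graph, an empty OBO lexicon yields zero mappings,
  and every SELECT on an empty graph returns zero rows. Ties in SPARQL
  results are broken by sorting the canonical term encodings.
- **Dates** are ISO-8601 calendar dates validated at parse time; source
  timestamps are truncated to dates. Language tags are lowercased and
  passed through without BCP-47 mapping.
- The RDF substrate (triple store, Turtle writer/reader, SPARQL subset of
  basic graph patterns + `OPTIONAL` + `SELECT`/`ASK`/`DISTINCT`) is
  implemented in the package; the test suite additionally parses every
  emitted file with an independent RDF library and checks isomorphism, so
  conformance does not rest on the package's own reader.

## What the synthetic fixtures emulate

The exemplar bundle reproduces the worked example: twelve codes (winter
soft wheat and its crop groups, the wheat and leaf-miner taxa with one
host relation and one quarantine categorization, the brassica species with
shared crop groups, the treatment-methods group) plus a one-term OBO
lexicon. Literal values the sources do not pin down (dates, alternative
labels) are synthesized sentinels such as `2001-01-01` and are not claims
about the real database.

The random generator emulates the *shape* of the coding system: a seeded
taxonomic forest (default depth ≤ 6) with Latin-like binomials and
multilingual synonyms, non-taxonomic and commodity groups with part-of
chains and associations, host–pest relations over the standard category
registry, replacement chains (never cycles) of inactive codes, and
categorization statuses of which a configurable fraction (default 0.2)
carries q-lists deliberately missing from the scheme to exercise the
maintenance warning path. A configurable fraction (default 0.5) of
taxonomic names is mirrored into the companion lexicon so enrichment always
has hits. Defaults (100 taxa, 20 groups, 30 relations, 20 statuses, 10
replacements) are sized like a small regional slice of the real system; the
test suite uses 200-taxon bundles over ten seeds and a 500-code bundle for
the deprecation check, sizes at which every property is exercised while the
whole suite stays inside a couple of minutes.

What passing these tests does **not** show: the generator does not model
the real database's scale (hundreds of thousands of codes), its name
distributions, encoding quirks of real exports, or real taxonomic
semantics; and lexical enrichment is exact-match only, so recall on real
common names (spelling variants, authority suffixes) will be lower than on
fixtures. Full-scale metrics of the published ontology depend on the
database version and are out of scope.

## Known limitations

- No OWL reasoning: subsumption is asserted, never inferred.
- The Turtle reader covers the subset the writer emits (plus labelled blank
  nodes); it is not a general-purpose Turtle parser.
- Two names of one code that are identical in role, text and language but
  differ only in metadata collapse into one asserted triple; the walk-back
  then sees merged annotations. The generators avoid this; real exports
  with such duplicates would need pre-deduplication.
- The SQLite dialect requires a system `python` interpreter (stdlib
  `sqlite3`); the CSV dialect has no external dependency.
- The q-list→categorization map and code-type groups are compile-time
  configuration; a graph walk-back recovers them only as far as they are
  observable in the emitted triples, so `kb_from_graph()` accepts the
  original config for exact reconstruction.
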