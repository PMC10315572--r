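# eppoforge

Compile an EPPO-style plant/pest coding system into an OWL 2 ontology.

EPPO codes are short 5–6 character identifiers for plants, pests and
pathogens, maintained as the worldwide reference for plant-protection work.
The coding system is distributed as relational artifacts — a code table with
multilingual names and synonyms, a replaced-codes history, per-country
phytosanitary categorization lists, and host–pest relation records — which
makes it awkward to query, link or enrich. `eppoforge` is for knowledge
engineers and bioinformaticians who want that content as a semantic
artifact: it ingests the relational sources, assembles and validates an
in-memory knowledge base, compiles it into an OWL ontology with
deterministic Turtle serialization, enriches it with lexical
cross-references to an external taxonomy (NCBITaxon-style OBO lexicon), and
verifies the result with a SPARQL competency-question harness.

## The model

Codes are modelled as OWL classes (OWL 2 punning), subdivided into
`TaxonomicCode`, `NonTaxonomicCode` and `CommodityGroup` under a common
`EPPOCode` root, with the code hierarchy carried by `rdfs:subClassOf`.
Each code class carries:

- `rdfs:label` (preferred scientific name, language-tagged `@la`),
  `skos:altLabel` and `oboInOwl:hasExactSynonym` for other names; names with
  provenance (creation/modification dates, naming authority, activity flag)
  are annotated via `owl:Axiom` reification nodes;
- `dc:identifier`, `dcterms:created`/`dcterms:modified`, an `isActive`
  boolean and an optional `rdfs:comment` definition;
- `has_eppo_type` to its code-type class, and for taxonomic codes
  `has_taxonomy` (level class), `has_taxonomy_level` (integer distance to the
  hierarchy root) and `has_categorization` links to categorization-status
  classes, which in turn carry `has_status` into the expert categorization
  hierarchy plus continent/country/ISO/q-list/year annotations;
- `obo:BFO_0000050` (part of) and `sio:SIO_001403` (is associated with) for
  group membership and association links;
- one `has_pest_type_<category>` / `has_host_type_<category>` inverse
  subproperty pair of `has_pest`/`has_host` per relation category, asserted
  in both directions for every host–pest record;
- for superseded codes, the deprecation pattern `isActive false` +
  `owl:deprecated true` + `obo:IAO_0100001` (term replaced by).

Enrichment matches every code annotation against the term names and exact
synonyms of an OBO lexicon on exact normalized strings (casefolded,
whitespace-collapsed, punctuation-stripped) and injects
`oboInOwl:hasDbXref` triples.

## Worked example

```r
library(eppoforge)

dir <- tempfile()
bundle <- exemplar_bundle(dir)         # writes the worked-example sources
kb <- read_bundle(bundle)
kb
#> <eppo_kb: 12 codes (6 taxonomic), 1 relations, 1 categorizations, 0 replacements>

graph <- build_graph(kb)
graph
#> <rdf_graph: 233 triples, 11 prefixes>

enr <- enrich_graph(graph, kb, bundle$lexicon_path)
enr$report
#> $added
#> [1] 2
#> $skipped_ambiguous
#> [1] 0
#> $unmatched_codes
#> [1] 10

run_builtin_suite(enr$graph)
#> <eppo_cq_report: 4/4 passed>
#>   PASS CQ1
#>   PASS CQ2
#>   PASS CQ3
#>   PASS CQ4

serialize_graph(enr$graph, "eppo.ttl")  # deterministic, sorted Turtle
```

The twelve exemplar codes cover winter soft wheat (`TRZAW`, a non-taxonomic
crop code, part of the soft-wheat crops group `3SWHC`), the wheat taxon
`TRZAX` under genus `1TRZG`, the rice leaf miner `AGMYOR` (host relation to
`TRZAX`, quarantine categorization), two brassica species sharing the leafy
brassica crops group, and the treatment-methods group with its member
`3BRUSM` ("brushing"). The two injected cross-references tie `TRZAW` and
`TRZAX` to *Triticum aestivum* (`obo:NCBITaxon_4565`) in the companion
lexicon. The four built-in competency questions ask, respectively, which
taxon is associated with `TRZAW` (answer: `.../EPPO/TRZAX`), which crop
groups `BRSJU` belongs to, whether `BRSJU` and `BRSRW` share a crop group
(true, via `3LFBC`), and which codes are part of `3TMETM` (the brushing
treatment with its description).

A command-line interface over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/eppoforge.R", package="eppoforge"))')
Rscript $CLI fixture --exemplar --o bundle_dir
Rscript $CLI build --bundle bundle_dir --o eppo.ttl
Rscript $CLI enrich --ontology eppo.ttl --lexicon bundle_dir/taxonomy.obo --o eppo_enriched.ttl
Rscript $CLI validate --ontology eppo_enriched.ttl   # exit 0 iff all CQs pass
Rscript $CLI metrics --ontology eppo_enriched.ttl
```

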