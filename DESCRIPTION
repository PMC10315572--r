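Package: eppoforge
Title: Compile EPPO-Style Plant and Pest Coding Systems into an OWL Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to transform the relational sources of an EPPO-style
    plant-protection coding system (code tables with multilingual names,
    replaced-code history, phytosanitary categorization lists, host-pest
    relations and an expert categorization scheme) into an OWL 2 ontology
    serialized as deterministic Turtle. Includes lexical enrichment with
    cross-references to an external taxonomy lexicon in OBO format, a
    SPARQL-based competency-question harness for validating emitted
    ontologies, seeded synthetic fixture generation, and maintenance
    tooling that diffs knowledge-base versions and flags categorization
    lists requiring expert classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
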