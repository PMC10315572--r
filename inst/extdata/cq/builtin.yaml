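# Built-in competency questions for ontologies built from KBs that contain
# the worked-example codes. Variables referenced in `expected` must appear in
# the SELECT projection; string answers are compared after language-tag
# stripping, IRIs exactly.
- id: CQ1
  question: >
    Which taxonomic code is associated with non-taxonomic code "TRZAW"?
  compare: set_equal
  query: |
    PREFIX sio: <http://semanticscience.org/resource/>
    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
    SELECT ?taxon WHERE {
      ?taxon sio:SIO_001403 eppo:TRZAW .
    }
  expected:
    - taxon: https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/TRZAX
- id: CQ2
  question: >
    List the non-taxonomic EPPO codes and names associated with the species
    "Brassica juncea" (BRSJU). Is this species part of any crop group?
  compare: set_equal
  query: |
    PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
    PREFIX sio: <http://semanticscience.org/resource/>
    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
    SELECT ?code ?name WHERE {
      eppo:BRSJU sio:SIO_001403 ?code .
      ?code rdfs:label ?name .
    }
  expected:
    - code: https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/3LFBC
      name: leafy brassica crops
    - code: https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/3MUSC
      name: mustard crops
- id: CQ3
  question: >
    Do "BRSJU" and "BRSRW" belong to a common crop group (leafy brassica
    crops, 3LFBC)?
  compare: boolean
  query: |
    PREFIX sio: <http://semanticscience.org/resource/>
    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
    ASK {
      eppo:BRSJU sio:SIO_001403 ?group .
      eppo:BRSRW sio:SIO_001403 ?group .
    }
  expected: true
- id: CQ4
  question: >
    List all EPPO codes (with names and descriptions) that are part of the
    non-taxonomic code group "treatment methods" (3TMETM).
  compare: set_equal
  query: |
    PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
    PREFIX obo: <http://purl.obolibrary.org/obo/>
    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
    SELECT ?code ?name ?description WHERE {
      ?code obo:BFO_0000050 eppo:3TMETM .
      ?code rdfs:label ?name .
      OPTIONAL { ?code rdfs:comment ?description . }
    }
  expected:
    - code: https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/3BRUSM
      name: brushing
      description: >-
        Application of a liquid product or powder with a brush, e.g., tree
        trunk application of fungicide in citrus or local treatment of single
        weeds in a crop stand
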