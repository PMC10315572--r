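RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
OWL_DEPRECATED <- "http://www.w3.org/2002/07/owl#deprecated"
TERM_REPLACED <- "http://purl.obolibrary.org/obo/IAO_0100001"

test_that("IRI minting is deterministic and collision-checked", {
  v <- eppo_vocabulary()
  expect_equal(mint_iri(v, "code", "TRZAX"),
               "https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/TRZAX")
  expect_identical(mint_iri(v, "code", "TRZAX"), mint_iri(v, "code", "TRZAX"))
  expect_error(mint_iri(v, "code", ""), class = "eppo_mint_error")

  # two statuses differing only in year get distinct IRIs via the year suffix
  kb <- assemble_kb(
    list(tiny_code("AAAAA", level_name = "Species", level_distance = 0L)),
    categorizations = rbind(
      categorization_status("AAAAA", "A1 list", iso_code = "ES", year_added = 2001),
      categorization_status("AAAAA", "A1 list", iso_code = "ES", year_added = 2007)
    ),
    scheme = categorization_scheme(
      data.frame(id = "QuarantinePest", parent = NA, stringsAsFactors = FALSE),
      c("A1 list" = "QuarantinePest")),
    levels = taxonomy_levels("Species"),
    types = exemplar_types_for_tests()
  )
  g <- build_graph(kb)
  statuses <- g$triples$s[g$triples$p == RDFS_SUBCLASS &
                            g$triples$o == eppo_iri("CategorizationStatus")]
  expect_length(unique(statuses), 2L)
  expect_setequal(unique(statuses),
                  paste0(eppo_iri("AAAAA_CAT_a1_list_es_"), c(2001, 2007)))
})

test_that("the exemplar graph realizes the worked-example structure", {
  ex <- cached_exemplar()
  g <- ex$graph
  # TRZAW: non-taxonomic, part of the soft wheat crops group
  expect_true(rdf_has(g, eppo_iri("TRZAW"), RDFS_SUBCLASS,
                      eppo_iri("NonTaxonomicCode")))
  expect_true(rdf_has(g, eppo_iri("TRZAW"),
                      "http://purl.obolibrary.org/obo/BFO_0000050",
                      eppo_iri("3SWHC")))
  # TRZAX: subclass of the genus code, associated with TRZAW
  expect_true(rdf_has(g, eppo_iri("TRZAX"), RDFS_SUBCLASS, eppo_iri("1TRZG")))
  expect_true(rdf_has(g, eppo_iri("TRZAX"),
                      "http://semanticscience.org/resource/SIO_001403",
                      eppo_iri("TRZAW")))
  # host-pest pair in both directions
  expect_true(rdf_has(g, eppo_iri("TRZAX"), eppo_iri("has_pest_type_host"),
                      eppo_iri("AGMYOR")))
  expect_true(rdf_has(g, eppo_iri("AGMYOR"), eppo_iri("has_host_type_host"),
                      eppo_iri("TRZAX")))
  # AGMYOR's quarantine categorization
  status <- g$triples$o[g$triples$s == eppo_iri("AGMYOR") &
                          g$triples$p == eppo_iri("has_categorization")]
  expect_length(status, 1L)
  expect_true(rdf_has(g, status, eppo_iri("has_status"), eppo_iri("QuarantinePest")))
  expect_true(rdf_has(g, status, eppo_iri("has_categorization_iso_code"), "ES"))
})

test_that("every code class carries exactly one label and identifier equal to its code", {
  ex <- cached_exemplar()
  df <- ex$graph$triples
  for (code in names(ex$kb$codes)) {
    s <- eppo_iri(code)
    labels <- df[df$s == s & df$p == "http://www.w3.org/2000/01/rdf-schema#label", ]
    ids <- df[df$s == s & df$p == "http://purl.org/dc/elements/1.1/identifier", ]
    expect_equal(nrow(labels), 1L)
    expect_equal(nrow(ids), 1L)
    expect_equal(ids$o, code)
  }
})

test_that("name metadata is reified as owl:Axiom annotation nodes", {
  ex <- cached_exemplar()
  df <- ex$graph$triples
  # the Danish synonym carries created + isActive on its axiom node
  node <- df$s[df$p == "http://www.w3.org/2002/07/owl#annotatedTarget" &
                 df$o == "vinterhvede"]
  expect_length(node, 1L)
  ann <- df[df$s == node, ]
  expect_true("http://www.w3.org/2002/07/owl#Axiom" %in% ann$o)
  expect_equal(ann$o[ann$p == "http://purl.org/dc/terms/created"], "2002-02-02")
  expect_equal(ann$o[ann$p == eppo_iri("isActive")], "true")
  # 4 structural triples + 2 annotations
  expect_equal(nrow(ann), 6L)
  # the authority annotation on the leaf-miner's preferred name
  node2 <- df$s[df$p == "http://www.w3.org/2002/07/owl#annotatedTarget" &
                  df$o == "Agromyza oryzae"]
  expect_equal(df$o[df$s == node2 & df$p == eppo_iri("has_authority")], "Munakata")
  # a plain name gets no axiom node
  expect_false("brushing" %in% df$o[df$p ==
    "http://www.w3.org/2002/07/owl#annotatedTarget"])
})

test_that("annotate_literal adds the asserted triple and conditional reification", {
  g <- rdf_graph(c(default_prefixes(), eppo = eppo_iri("")))
  g <- rdf_add(g, eppo_iri("AAAAA"),
               "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
               "http://www.w3.org/2002/07/owl#Class")
  n0 <- rdf_size(g)
  plain <- name_record("plainname", "en", "synonym")
  g1 <- annotate_literal(g, eppo_iri("AAAAA"),
                         "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym",
                         plain)
  expect_equal(rdf_size(g1) - n0, 1L)

  rich <- name_record("richname", "da", "synonym", created = "2002-02-02")
  g2 <- annotate_literal(g, eppo_iri("AAAAA"),
                         "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym",
                         rich)
  # 1 asserted + 4 structural + created + isActive
  expect_equal(rdf_size(g2) - n0, 7L)
  expect_error(annotate_literal(g, eppo_iri("QQQQQ"),
                                "http://www.w3.org/2000/01/rdf-schema#label",
                                plain),
               class = "eppo_precondition_error")
})

test_that("an empty KB emits a T-Box-only graph with zero code classes", {
  kb <- assemble_kb(scheme = exemplar_kb()$scheme, levels = exemplar_kb()$levels,
                    types = exemplar_kb()$types)
  g <- build_graph(kb)
  df <- g$triples
  ids <- df[df$p == "http://purl.org/dc/elements/1.1/identifier", ]
  code_classes <- ids$s[ids$s == paste0(eppo_iri(""), ids$o) &
                          grepl("^[0-9A-Z]{5,6}$", ids$o)]
  expect_length(code_classes, 0L)
  # the schema classes are present
  expect_true(rdf_has(g, eppo_iri("EPPOCode"), o = "http://www.w3.org/2002/07/owl#Class"))
  m <- ontology_metrics(g)
  expect_equal(m$classes,
               8L + nrow(kb$scheme$nodes) + nrow(kb$levels) + nrow(kb$types))
})

test_that("metrics match independent counting oracles and are additive", {
  ex <- cached_exemplar()
  m <- ontology_metrics(ex$graph)
  tbox_classes <- 8L + nrow(ex$kb$scheme$nodes) + nrow(ex$kb$levels) +
    nrow(ex$kb$types)
  expect_equal(m$classes, tbox_classes + 12L + nrow(ex$kb$categorizations))
  expect_equal(m$axioms, rdf_size(ex$graph))
  # object properties: 8 core + one inverse pair per category
  expect_equal(m$object_properties, 8L + 2L * length(ex$kb$categories))
  expect_equal(m$annotation_properties, 16L)
  expect_equal(m$datatype_properties, 1L)

  g2 <- rdf_add(ex$graph, eppo_iri("ZZZZZ"),
                "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
                "http://www.w3.org/2002/07/owl#Class")
  expect_equal(ontology_metrics(g2)$classes, m$classes + 1L)
})

test_that("triple counts equal the per-record triple-budget oracle", {
  kb <- random_kb(fixture_spec(seed = 3, n_taxa = 200, n_nontaxonomic = 30,
                               n_relations = 40, n_categorizations = 25,
                               n_replacements = 12))
  g <- build_graph(kb)
  expect_equal(rdf_size(g), oracle_triple_budget(kb))
  ex <- cached_exemplar()
  expect_equal(rdf_size(ex$graph), oracle_triple_budget(ex$kb))
})

test_that("deprecation triples appear exactly on replaced codes", {
  kb <- random_kb(fixture_spec(seed = 4, n_taxa = 60, n_replacements = 8))
  g <- build_graph(kb)
  df <- g$triples
  replaced <- unique(kb$replacements$old_code)
  for (code in names(kb$codes)) {
    s <- eppo_iri(code)
    trio <- rdf_has(g, s, eppo_iri("isActive"), "false") &&
      rdf_has(g, s, OWL_DEPRECATED, "true") &&
      length(df$o[df$s == s & df$p == TERM_REPLACED]) > 0L
    expect_equal(trio, code %in% replaced, info = code)
  }
})

test_that("building an invalid KB is a precondition error", {
  kb <- tiny_kb(list(tiny_code("AAAAA", parent = "MISSNG")))
  expect_error(build_graph(kb), class = "eppo_precondition_error")
})

test_that("the emitted graph walks back to the source KB bit for bit", {
  ex <- cached_exemplar()
  cfg <- list(scheme = ex$kb$scheme, levels = ex$kb$levels, types = ex$kb$types)
  kb2 <- kb_from_graph(read_turtle(write_turtle(ex$graph)), config = cfg)
  expect_true(kb_equal(ex$kb, kb2))
})
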