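test_that("the association query returns exactly the wheat taxon", {
  ex <- cached_exemplar()
  res <- run_query(ex$graph, "
    PREFIX sio: <http://semanticscience.org/resource/>
    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
    SELECT ?taxon WHERE { ?taxon sio:SIO_001403 eppo:TRZAW . }")
  expect_equal(nrow(res), 1L)
  expect_equal(sparql_decode(res$taxon), eppo_iri("TRZAX"))
})

test_that("the shared-crop-group ASK is true on the exemplar graph", {
  ex <- cached_exemplar()
  expect_true(run_query(ex$graph, "
    PREFIX sio: <http://semanticscience.org/resource/>
    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
    ASK { eppo:BRSJU sio:SIO_001403 ?g . eppo:BRSRW sio:SIO_001403 ?g . }"))
})

test_that("per-question evaluation diffs observed against expected", {
  ex <- cached_exemplar()
  suite <- builtin_cq_suite()
  ids <- vapply(suite, function(q) q$id, "")

  cq4 <- suite[[which(ids == "CQ4")]]
  r4 <- evaluate_cq(ex$graph, cq4)
  expect_equal(r4$status, "pass")
  expect_true(any(grepl("3BRUSM", r4$observed, fixed = TRUE) &
                    grepl("brushing", r4$observed, fixed = TRUE)))

  # ablate the association triple backing CQ1 -> missing-row diff
  g_cut <- drop_triples(ex$graph, s = eppo_iri("TRZAX"),
                        p = "http://semanticscience.org/resource/SIO_001403",
                        o = eppo_iri("TRZAW"))
  r1 <- evaluate_cq(g_cut, suite[[which(ids == "CQ1")]])
  expect_equal(r1$status, "fail")
  expect_length(r1$diff$missing, 1L)

  # subset compare passes when expected is a strict subset of observed
  cq_sub <- competency_question(
    "CQX", "subset demo",
    "PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>
     PREFIX sio: <http://semanticscience.org/resource/>
     SELECT ?code WHERE { eppo:BRSJU sio:SIO_001403 ?code . }",
    expected = list(list(code = eppo_iri("3LFBC"))),
    compare = "subset")
  expect_equal(evaluate_cq(ex$graph, cq_sub)$status, "pass")
  cq_eq <- cq_sub
  cq_eq$compare <- "set_equal"
  expect_equal(evaluate_cq(ex$graph, cq_eq)$status, "fail")
})

test_that("the built-in suite passes on the exemplar and fails on an empty graph", {
  ex <- cached_exemplar()
  rep <- run_builtin_suite(ex$enriched)
  expect_equal(rep$passed, 4L)
  expect_equal(rep$failed, 0L)

  rep0 <- run_builtin_suite(rdf_graph())
  expect_equal(rep0$failed, 4L)
})

test_that("removing the turnip-rape association breaks only the shared-group CQ", {
  ex <- cached_exemplar()
  g_cut <- drop_triples(ex$graph, s = eppo_iri("BRSRW"),
                        p = "http://semanticscience.org/resource/SIO_001403",
                        o = eppo_iri("3LFBC"))
  rep <- run_builtin_suite(g_cut)
  statuses <- vapply(rep$results, function(r) r$status, "")
  expect_equal(unname(statuses[c("CQ1", "CQ2", "CQ4")]), rep("pass", 3L))
  expect_equal(unname(statuses[["CQ3"]]), "fail")
})

test_that("suite outcomes are invariant to triple insertion order", {
  ex <- cached_exemplar()
  set.seed(7)
  g_shuffled <- ex$graph
  g_shuffled$triples <- g_shuffled$triples[sample(nrow(g_shuffled$triples)), ,
                                           drop = FALSE]
  rep_a <- run_builtin_suite(ex$graph)
  rep_b <- run_builtin_suite(g_shuffled)
  expect_equal(vapply(rep_a$results, function(r) r$status, ""),
               vapply(rep_b$results, function(r) r$status, ""))
})

test_that("user suites load from YAML with boolean and row expectations", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "- id: U1",
    "  question: is the wheat class present",
    "  compare: boolean",
    "  query: |",
    "    PREFIX owl: <http://www.w3.org/2002/07/owl#>",
    "    PREFIX eppo: <https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/>",
    "    ASK { eppo:TRZAX a owl:Class . }",
    "  expected: true"), f)
  suite <- load_cq_suite(f)
  expect_length(suite, 1L)
  ex <- cached_exemplar()
  rep <- run_cq_suite(ex$graph, suite)
  expect_equal(rep$passed, 1L)
})
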