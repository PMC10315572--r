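DBXREF <- "http://www.geneontology.org/formats/oboInOwl#hasDbXref"

test_that("label normalization casefolds, collapses and strips, idempotently", {
  expect_equal(normalize_label("Triticum  Aestivum "), "triticum aestivum")
  expect_equal(normalize_label(""), "")
  expect_equal(normalize_label("  (Agromyza oryzae)  "), "agromyza oryzae")
  set.seed(99)
  junk <- replicate(50, paste0(
    sample(c(" ", "\t", "(", ")", ".", ",", LETTERS, letters, "é", "ø"), 12,
           replace = TRUE), collapse = ""))
  expect_identical(normalize_label(normalize_label(junk)), normalize_label(junk))
})

test_that("the OBO lexicon indexes names and exact synonyms", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: NCBITaxon:4565", "name: Triticum aestivum",
               "synonym: \"common wheat\" EXACT []",
               "synonym: \"bread wheat\" RELATED []", "",
               "[Term]", "id: NCBITaxon:9999", "name: Duplicatus namus", "",
               "[Term]", "id: NCBITaxon:9998", "name: Duplicatus namus", ""), f)
  idx <- build_taxon_index(f)
  expect_equal(idx$n_terms, 3L)
  hit <- eppoforge:::taxon_lookup(idx, "triticum aestivum")
  expect_equal(hit$taxon_iri, "http://purl.obolibrary.org/obo/NCBITaxon_4565")
  expect_equal(hit$field, "name")
  syn <- eppoforge:::taxon_lookup(idx, "common wheat")
  expect_equal(syn$field, "synonym")
  # RELATED synonyms are not indexed
  expect_null(eppoforge:::taxon_lookup(idx, "bread wheat"))
  # two terms sharing a name are both listed (multimap)
  dup <- eppoforge:::taxon_lookup(idx, "duplicatus namus")
  expect_equal(nrow(dup), 2L)

  empty <- tempfile(fileext = ".obo")
  writeLines("format-version: 1.2", empty)
  expect_equal(build_taxon_index(empty)$n_terms, 0L)

  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "name: no id here"), bad)
  expect_error(build_taxon_index(bad), class = "eppo_parse_error")
})

test_that("annotation matching finds the worked-example cross-reference", {
  ex <- cached_exemplar()
  idx <- build_taxon_index(ex$bundle$lexicon_path)
  maps <- match_annotations(ex$kb, idx)
  trzaw <- maps[maps$code == "TRZAW", ]
  expect_equal(trzaw$taxon_iri, "http://purl.obolibrary.org/obo/NCBITaxon_4565")
  expect_equal(trzaw$matched_text, "Triticum aestivum")
  expect_false(any(maps$ambiguous))
})

test_that("codes with no shared lexeme match nothing; multi-taxon hits are flagged", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: NCBITaxon:1", "name: Nomatchus anywherus"), f)
  ex <- cached_exemplar()
  expect_equal(nrow(match_annotations(ex$kb, build_taxon_index(f))), 0L)

  # one synonym hitting two distinct taxa -> both records ambiguous
  f2 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: NCBITaxon:11", "name: Sharedus namus", "",
               "[Term]", "id: NCBITaxon:12", "name: Otherus totallus",
               "synonym: \"Sharedus namus\" EXACT []"), f2)
  kb <- tiny_kb(list(code_record(
    "AAAAA", "taxonomic",
    rbind(tiny_names("Testus aaaaa"),
          name_record("Sharedus namus", "la", "synonym")),
    created = "2001-01-01", code_type = "PLS")))
  maps <- match_annotations(kb, build_taxon_index(f2))
  expect_equal(nrow(maps), 2L)
  expect_true(all(maps$ambiguous))
  # brute-force cross-join oracle agrees on the hit set
  g <- build_graph(kb)
  oracle <- oracle_expected_mappings(kb, f2)
  expect_equal(maps[, c("code", "taxon_iri")], oracle)
})

test_that("mapping application respects policy, monotonicity and soundness", {
  ex <- cached_exemplar()
  n0 <- rdf_size(ex$graph)
  res <- apply_mappings(ex$graph, ex$mappings, "all")
  expect_equal(res$report$added, nrow(ex$mappings))
  expect_equal(rdf_size(res$graph) - n0, res$report$added)
  # nothing removed or altered
  expect_equal(nrow(rdf_diff(ex$graph, res$graph)$only_a), 0L)
  expect_true(rdf_has(res$graph, eppo_iri("TRZAW"), DBXREF,
                      "http://purl.obolibrary.org/obo/NCBITaxon_4565"))

  # empty mappings leave the graph untouched
  res_empty <- apply_mappings(ex$graph, ex$mappings[0L, ], "all")
  expect_true(rdf_equal(ex$graph, res_empty$graph))

  # ambiguous-only input under unambiguous_only adds nothing
  amb <- ex$mappings
  amb$ambiguous <- TRUE
  res_amb <- apply_mappings(ex$graph, amb, "unambiguous_only")
  expect_equal(res_amb$report$added, 0L)
  expect_equal(res_amb$report$skipped_ambiguous, nrow(amb))
  expect_true(rdf_equal(ex$graph, res_amb$graph))

  # a mapping onto a code absent from the graph is an application error
  foreign <- data.frame(code = "ZZZZZ", matched_text = "x",
                        taxon_iri = "http://purl.obolibrary.org/obo/NCBITaxon_1",
                        ambiguous = FALSE, stringsAsFactors = FALSE)
  expect_error(apply_mappings(ex$graph, foreign, "all"),
               class = "eppo_application_error")
})

test_that("every injected cross-reference is re-derivable from the lexicon", {
  spec <- fixture_spec(seed = 21, n_taxa = 80, n_nontaxonomic = 10)
  dir <- tempfile()
  b <- random_bundle(spec, dir)
  kb <- read_bundle(b)
  g <- build_graph(kb)
  res <- enrich_graph(g, kb, b$lexicon_path)
  injected <- res$graph$triples[res$graph$triples$p == DBXREF &
                                  res$graph$triples$o_kind == "iri", ]
  oracle <- oracle_expected_mappings(kb, b$lexicon_path)
  expect_equal(nrow(injected), nrow(oracle))
  expect_setequal(paste(injected$s, injected$o),
                  paste(eppo_iri(oracle$code), oracle$taxon_iri))
  # determinism: identical KB + lexicon give identical mapping sequences
  expect_identical(res$mappings,
                   match_annotations(kb, build_taxon_index(b$lexicon_path)))
})
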