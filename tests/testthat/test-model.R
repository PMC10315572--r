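test_that("exemplar knowledge base assembles with the worked-example content", {
  kb <- exemplar_kb()
  expect_s3_class(kb, "eppo_kb")
  expect_length(kb$codes, 12L)
  expect_setequal(names(kb$codes),
                  c("TRZAW", "TRZAX", "1TRZG", "3SWHC", "AGMYOR", "1AGMYG",
                    "BRSJU", "BRSRW", "3LFBC", "3MUSC", "3TMETM", "3BRUSM"))
  # the leaf-miner relation: AGMYOR is the pest, TRZAX the host
  expect_equal(nrow(kb$relations), 1L)
  expect_equal(kb$relations$pest, "AGMYOR")
  expect_equal(kb$relations$host, "TRZAX")
  expect_equal(kb$relations$category, "host")
  expect_equal(kb$categories, "host")
})

test_that("all-empty inputs assemble into an empty KB with config only", {
  kb <- assemble_kb(scheme = exemplar_scheme_small(), levels = taxonomy_levels(),
                    types = exemplar_types_for_tests())
  expect_length(kb$codes, 0L)
  expect_equal(nrow(kb$relations), 0L)
  expect_equal(nrow(kb$categorizations), 0L)
  expect_equal(nrow(validate_kb(kb)$errors), 0L)
})

test_that("duplicate identifiers and preferred names are rejected at assembly", {
  expect_error(assemble_kb(list(tiny_code("AAAAA"), tiny_code("AAAAA"))),
               "AAAAA", class = "eppo_assembly_error")
  two_pref <- rbind(name_record("Testus unus", "la"),
                    name_record("Testus duo", "la"))
  expect_error(code_record("AAAAB", "taxonomic", two_pref, "2001-01-01"),
               "preferred", class = "eppo_assembly_error")
})

test_that("record constructors enforce field invariants", {
  expect_error(tiny_code("aaa"), class = "eppo_row_error")        # syntax
  expect_error(tiny_code("TOOLONGCODE"), class = "eppo_row_error")
  expect_error(code_record("AAAAA", "taxonomic", tiny_names(), created = NA),
               class = "eppo_row_error")
  expect_error(code_record("AAAAA", "non_taxonomic", tiny_names(),
                           "2001-01-01", level_name = "Species"),
               class = "eppo_row_error")                          # level on non-taxon
  expect_error(code_record("AAAAA", "taxonomic", tiny_names(),
                           "2001-01-01", part_of = "BBBBB"),
               class = "eppo_row_error")                          # part_of on taxon
  expect_error(name_record("", "la"), class = "eppo_row_error")
  expect_error(host_pest_relation("AAAAA", "AAAAA", "host"),
               class = "eppo_row_error")
  expect_error(replacement_record("AAAAA", "AAAAA"), class = "eppo_row_error")
  expect_error(categorization_status("AAAAA", "q", year_added = 2010,
                                     year_deleted = 2005),
               class = "eppo_row_error")
})

test_that("validation accepts the exemplar and pinpoints constructed violations", {
  ex <- cached_exemplar()
  report <- validate_kb(ex$kb)
  expect_equal(nrow(report$errors), 0L)
  expect_equal(nrow(report$warnings), 0L)

  cyclic <- tiny_kb(list(tiny_code("AAAAA", parent = "BBBBB"),
                         tiny_code("BBBBB", parent = "AAAAA")))
  rep2 <- validate_kb(cyclic)
  cyc_err <- rep2$errors[rep2$errors$rule == "parent_cycle", ]
  expect_equal(nrow(cyc_err), 1L)
  expect_match(cyc_err$message, "AAAAA")
  expect_match(cyc_err$message, "BBBBB")

  kb3 <- assemble_kb(list(tiny_code("AAAAA")),
                     categorizations = categorization_status("AAAAA", "Lista nueva"),
                     scheme = exemplar_scheme_small(),
                     types = exemplar_types_for_tests())
  rep3 <- validate_kb(kb3)
  expect_equal(nrow(rep3$errors), 0L)
  expect_equal(rep3$warnings$rule, "q_list_unmapped")
  expect_match(rep3$warnings$message, "Lista nueva")
  # strict mode escalates the warning
  expect_gt(nrow(validate_kb(kb3, strict = TRUE)$errors), 0L)
})

test_that("missing parents are errors unless lenient", {
  kb <- tiny_kb(list(tiny_code("AAAAA", parent = "ZZZZZ")))
  expect_equal(validate_kb(kb)$errors$rule, "parent_missing")
  lenient <- validate_kb(kb, lenient = TRUE)
  expect_equal(nrow(lenient$errors), 0L)
  expect_equal(lenient$warnings$rule, "parent_missing")
  # the emitter then attaches the orphan under its kind root
  g <- build_graph(kb, lenient = TRUE)
  expect_true(rdf_has(g, s = eppo_iri("AAAAA"),
                      p = "http://www.w3.org/2000/01/rdf-schema#subClassOf",
                      o = eppo_iri("TaxonomicCode")))
})

test_that("replacement resolution follows chains and reports cycles", {
  chain <- tiny_kb(
    list(tiny_code("AAAAX"), tiny_code("AAAAY"), tiny_code("AAAAZ")),
    replacements = rbind(replacement_record("AAAAX", "AAAAY"),
                         replacement_record("AAAAY", "AAAAZ"))
  )
  expect_equal(resolve_replacement(chain, "AAAAZ"), "AAAAZ") # identity for active
  expect_equal(resolve_replacement(chain, "AAAAX"), "AAAAZ") # transitive follow
  expect_equal(resolve_replacement(chain, resolve_replacement(chain, "AAAAX")),
               resolve_replacement(chain, "AAAAX"))          # idempotent on result
  expect_error(resolve_replacement(chain, "QQQQQ"), class = "eppo_lookup_error")

  cyc <- tiny_kb(
    list(tiny_code("AAAAX"), tiny_code("AAAAY")),
    replacements = rbind(replacement_record("AAAAX", "AAAAY"),
                         replacement_record("AAAAY", "AAAAX"))
  )
  expect_error(resolve_replacement(cyc, "AAAAX"), "AAAAX",
               class = "eppo_cycle_error")
})

test_that("lineage walks to the root and matches a brute-force oracle", {
  ex <- cached_exemplar()
  expect_equal(lineage(ex$kb, "TRZAX"), "1TRZG")
  expect_equal(lineage(ex$kb, "1TRZG"), character(0))
  expect_error(lineage(ex$kb, "QQQQQ"), class = "eppo_lookup_error")

  kb <- random_kb(fixture_spec(seed = 5, n_taxa = 120, n_nontaxonomic = 15))
  for (code in names(kb$codes)) {
    expect_equal(length(lineage(kb, code)), oracle_depth(kb, code))
  }
})

test_that("the parent graph of a validated KB is a forest", {
  kb <- random_kb(fixture_spec(seed = 6, n_taxa = 150))
  expect_equal(nrow(validate_kb(kb)$errors), 0L)
  parents <- vapply(kb$codes, function(r) r$parent, "")
  n_roots <- sum(is.na(parents))
  expect_equal(sum(!is.na(parents)), length(kb$codes) - n_roots)
  for (code in names(kb$codes)) {
    expect_false(oracle_is_ancestor(kb, code, code))
  }
})
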