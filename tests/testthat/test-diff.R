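test_that("diffing a KB against itself is empty", {
  ex <- cached_exemplar()
  report <- diff_kb(ex$kb, ex$kb)
  expect_true(change_report_empty(report))
})

test_that("constructed additions, deletions and edits are recovered exactly", {
  kb_old <- random_kb(fixture_spec(seed = 31, n_taxa = 80, n_nontaxonomic = 10,
                                   n_relations = 15, n_categorizations = 10,
                                   n_replacements = 5))
  codes <- kb_old$codes

  # delete codes nothing else references
  referenced <- unique(c(
    unlist(lapply(codes, function(r) c(r$parent, r$part_of, r$associated_with))),
    kb_old$relations$pest, kb_old$relations$host,
    kb_old$categorizations$subject,
    kb_old$replacements$old_code, kb_old$replacements$new_code))
  deletable <- setdiff(names(codes), referenced)[1:5]
  new_codes <- codes[setdiff(names(codes), deletable)]

  added <- paste0("NEW", sprintf("%02d", 1:10))
  for (code in added) {
    new_codes[[code]] <- code_record(code, "taxonomic",
                                     name_record(paste("Novus", tolower(code)), "la"),
                                     created = "2021-06-01", code_type = "PLS",
                                     level_name = "Species", level_distance = 0L)
  }
  # one field-level edit on a surviving code
  edited <- setdiff(names(codes), c(deletable, referenced))[6]
  r <- new_codes[[edited]]
  new_codes[[edited]] <- code_record(r$code, r$kind, r$names, r$created,
                                     modified = "2022-01-01", active = r$active,
                                     parent = r$parent, code_type = r$code_type,
                                     level_name = r$level_name,
                                     level_distance = r$level_distance,
                                     part_of = r$part_of,
                                     associated_with = r$associated_with,
                                     comment = r$comment)

  new_cats <- rbind(kb_old$categorizations,
                    categorization_status(added[1], "Lista nueva",
                                          iso_code = "PT", year_added = 2022))
  kb_new <- assemble_kb(new_codes, kb_old$relations, new_cats,
                        kb_old$replacements, kb_old$scheme, kb_old$levels,
                        kb_old$types)
  expect_equal(nrow(validate_kb(kb_new)$errors), 0L)

  report <- diff_kb(kb_old, kb_new)
  expect_equal(report$added_codes, sort(added))
  expect_equal(report$removed_codes, sort(deletable))
  expect_equal(names(report$modified_codes), edited)
  expect_equal(report$modified_codes[[edited]], "modified")
  expect_equal(report$new_q_lists, "Lista nueva")
  expect_length(report$new_relation_categories, 0L)

  # anti-symmetry of additions and removals
  rev <- diff_kb(kb_new, kb_old)
  expect_equal(report$added_codes, rev$removed_codes)
  expect_equal(report$removed_codes, rev$added_codes)
})

test_that("new replacements surface as newly deprecated codes", {
  kb_old <- tiny_kb(list(tiny_code("AAAAX"), tiny_code("AAAAY")))
  kb_new <- tiny_kb(list(tiny_code("AAAAX"), tiny_code("AAAAY")),
                    replacements = replacement_record("AAAAX", "AAAAY"))
  report <- diff_kb(kb_old, kb_new)
  expect_equal(report$newly_deprecated, "AAAAX")
})

test_that("unclassified q-lists are deduplicated and sorted", {
  ex <- cached_exemplar()
  expect_equal(flag_unclassified(ex$kb), character(0))
  kb <- assemble_kb(
    list(tiny_code("AAAAA")),
    categorizations = rbind(
      categorization_status("AAAAA", "Lista X", iso_code = "ES"),
      categorization_status("AAAAA", "Lista X", iso_code = "FR")),
    scheme = categorization_scheme(),
    types = exemplar_types_for_tests())
  expect_equal(flag_unclassified(kb), "Lista X")
})

test_that("semantic diff agrees with a Turtle-level diff on changed code IRIs", {
  kb_old <- random_kb(fixture_spec(seed = 33, n_taxa = 40, n_nontaxonomic = 5,
                                   n_relations = 8, n_categorizations = 5,
                                   n_replacements = 0))
  codes <- kb_old$codes
  referenced <- unique(c(
    unlist(lapply(codes, function(r) c(r$parent, r$part_of, r$associated_with))),
    kb_old$relations$pest, kb_old$relations$host,
    kb_old$categorizations$subject))
  gone <- setdiff(names(codes), referenced)[1]
  kb_new <- assemble_kb(codes[setdiff(names(codes), gone)], kb_old$relations,
                        kb_old$categorizations, kb_old$replacements,
                        kb_old$scheme, kb_old$levels, kb_old$types)
  report <- diff_kb(kb_old, kb_new)
  d <- rdf_diff(build_graph(kb_old), build_graph(kb_new))
  changed_iris <- unique(c(d$only_a$s, d$only_b$s))
  changed_codes <- sub("^.*EPPO/", "", changed_iris[grepl("^[0-9A-Z]{5,6}$",
                                                          sub("^.*EPPO/", "", changed_iris))])
  expect_setequal(changed_codes, c(report$added_codes, report$removed_codes,
                                   names(report$modified_codes)))
})
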