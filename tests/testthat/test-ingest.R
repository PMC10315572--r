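test_that("the exemplar bundle parses into the twelve worked-example records", {
  ex <- cached_exemplar()
  records <- parse_code_table(ex$bundle$code_table_path, ex$bundle$dialect)
  expect_length(records, 12L)
  trzaw <- records[[which(vapply(records, function(r) r$code, "") == "TRZAW")]]
  expect_equal(trzaw$kind, "non_taxonomic")
  expect_equal(trzaw$names$text[trzaw$names$role == "preferred"],
               "Triticum aestivum (winter)")
  # common names in several languages, including the Danish synonym
  expect_true("vinterhvede" %in% trzaw$names$text)
  expect_equal(trzaw$names$language[trzaw$names$text == "vinterhvede"], "da")
  expect_equal(trzaw$part_of, "3SWHC")
})

test_that("empty but well-formed tables parse to empty collections", {
  dir <- tempfile()
  write_bundle(assemble_kb(types = exemplar_types_for_tests()), dir)
  expect_length(parse_code_table(dir, "csv"), 0L)
  expect_equal(nrow(parse_replaced_codes(file.path(dir, "replaced.csv"))), 0L)
  expect_equal(nrow(parse_categorization_list(file.path(dir, "categorizations.csv"))), 0L)
  rels <- parse_host_pest_relations(file.path(dir, "relations.json"))
  expect_equal(nrow(rels), 0L)
  expect_equal(attr(rels, "categories"), character(0))
})

test_that("csv and sqlite dialects of one bundle parse record-for-record equal", {
  kb <- random_kb(fixture_spec(seed = 11, n_taxa = 40, n_nontaxonomic = 10,
                               n_replacements = 4))
  d_csv <- tempfile(); d_sql <- tempfile()
  b_csv <- write_bundle(kb, d_csv, "csv")
  b_sql <- write_bundle(kb, d_sql, "sqlite")
  r_csv <- parse_code_table(b_csv$code_table_path, "csv")
  r_sql <- parse_code_table(b_sql$code_table_path, "sqlite")
  expect_equal(r_csv, r_sql)
  expect_true(kb_equal(read_bundle(b_csv), read_bundle(b_sql)))
})

test_that("parsing is order-stable across re-parses", {
  ex <- cached_exemplar()
  r1 <- parse_code_table(ex$bundle$code_table_path, ex$bundle$dialect)
  r2 <- parse_code_table(ex$bundle$code_table_path, ex$bundle$dialect)
  expect_identical(r1, r2)
})

test_that("schema and row errors carry the offending column or row", {
  dir <- tempfile(); dir.create(dir)
  writeLines("code,kind", file.path(dir, "codes.csv"))
  writeLines(paste(c("code,text,language,role,created,modified,active,authority"),
                   collapse = ""), file.path(dir, "names.csv"))
  writeLines("code,link_kind,target", file.path(dir, "links.csv"))
  expect_error(parse_code_table(dir, "csv"), "created",
               class = "eppo_schema_error")

  dir2 <- tempfile(); dir.create(dir2)
  writeLines(c("code,kind,created,modified,active,parent,code_type,level_name,level_distance,comment",
               "AAAAA,taxonomic,not-a-date,,true,,PLS,Species,0,"),
             file.path(dir2, "codes.csv"))
  writeLines(c("code,text,language,role,created,modified,active,authority",
               "AAAAA,Testus,la,preferred,,,true,"), file.path(dir2, "names.csv"))
  writeLines("code,link_kind,target", file.path(dir2, "links.csv"))
  expect_error(parse_code_table(dir2, "csv"), "not-a-date",
               class = "eppo_row_error")
})

test_that("replaced-codes rows parse and self-replacements are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("old_code,new_code,date", "AAAAB,AAAAC,2020-01-01"), f)
  reps <- parse_replaced_codes(f)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$old_code, "AAAAB")
  expect_equal(reps$date, "2020-01-01")

  writeLines("old_code,new_code,date", f)
  expect_equal(nrow(parse_replaced_codes(f)), 0L)

  writeLines(c("old_code,new_code,date", "AAAAB,AAAAB,"), f)
  expect_error(parse_replaced_codes(f), class = "eppo_row_error")
})

test_that("categorization lists parse blanks as absent and reject bad years", {
  f <- tempfile(fileext = ".csv")
  header <- "code,q_list,continent,country,iso_code,year_added,year_deleted,year_trans"
  writeLines(c(header, "AGMYOR,A1 list,Europe,Spain,ES,2002,,"), f)
  cats <- parse_categorization_list(f)
  expect_equal(cats$subject, "AGMYOR")
  expect_equal(cats$q_list, "A1 list")
  expect_equal(cats$year_added, 2002L)
  expect_true(is.na(cats$year_deleted))

  writeLines(c(header, "AGMYOR,A1 list,,,,,,"), f)
  blank <- parse_categorization_list(f)
  expect_true(all(is.na(c(blank$continent, blank$country, blank$iso_code,
                          blank$year_added))))

  writeLines(c(header, "AGMYOR,A1 list,,,,2010,2005,"), f)
  expect_error(parse_categorization_list(f), class = "eppo_row_error")
  writeLines(c(header, "AGMYOR,A1 list,,,,soon,,"), f)
  expect_error(parse_categorization_list(f), "soon", class = "eppo_row_error")
})

test_that("host-pest relations parse and register categories on the fly", {
  f <- tempfile(fileext = ".json")
  writeLines('[{"pest":"AGMYOR","host":"TRZAX","category":"host"},
               {"pest":"AAAAA","host":"BBBBB","category":"Alternate"}]', f)
  rels <- parse_host_pest_relations(f)
  expect_equal(nrow(rels), 2L)
  expect_equal(rels$category[rels$pest == "AGMYOR"], "host")
  expect_true("alternate" %in% attr(rels, "categories"))

  writeLines("[]", f)
  expect_equal(nrow(parse_host_pest_relations(f)), 0L)

  writeLines('[{"pest":"AGMYOR","category":"host"}]', f)
  expect_error(parse_host_pest_relations(f), "host",
               class = "eppo_row_error")
  writeLines("{not json", f)
  expect_error(parse_host_pest_relations(f), class = "eppo_parse_error")
})

test_that("scheme config parses the expert hierarchy and rejects cycles", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("categorizations:",
               "  - id: QuarantineOrganism",
               "  - id: QuarantinePest",
               "    parent: QuarantineOrganism",
               "q_lists:",
               "  A1 list: QuarantinePest"), f)
  scheme <- parse_categorization_scheme(f)
  expect_equal(nrow(scheme$nodes), 2L)
  expect_equal(scheme$nodes$parent[scheme$nodes$id == "QuarantinePest"],
               "QuarantineOrganism")
  expect_equal(unname(scheme$q_list_map[["A1 list"]]), "QuarantinePest")

  writeLines(c("categorizations:", "  - id: OnlyNode"), f)
  empty_map <- parse_categorization_scheme(f)
  expect_equal(nrow(empty_map$nodes), 1L)
  expect_length(empty_map$q_list_map, 0L)

  writeLines(c("categorizations:", "  - id: Selfish", "    parent: Selfish"), f)
  expect_error(parse_categorization_scheme(f), class = "eppo_config_error")
})
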