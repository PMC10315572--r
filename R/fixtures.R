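#' @title Synthetic source bundles
#'
#' @description
#' Generators for complete, self-contained source bundles so the whole
#' pipeline is testable without downloading anything: the worked-example
#' bundle (the twelve wheat / leaf-miner / brassica / treatment-method codes
#' with their associations, one host-pest relation, one quarantine
#' categorization and a companion taxonomy lexicon) and seeded random
#' EPPO-like bundles (a taxonomic forest, non-taxonomic and commodity
#' groups, multilingual synonyms, replacement chains and categorization
#' statuses, a configurable fraction of which carry deliberately unmapped
#' q-lists to exercise the maintenance warning path). Generation is a pure
#' function of the fixture spec: the same seed always yields byte-identical
#' bundles. Dates and labels that the coding system does not pin down are
#' synthesized sentinels (e.g. created 2001-01-01), not real-world claims.
#'
#' @name fixture_gen
NULL

BRUSHING_COMMENT <- paste(
  "Application of a liquid product or powder with a brush, e.g., tree trunk",
  "application of fungicide in citrus or local treatment of single weeds in",
  "a crop stand"
)

exemplar_levels <- function() {
  taxonomy_levels(c("Genus", "Species"), c("NCBITaxon:genus", "NCBITaxon:species"))
}

exemplar_types <- function() {
  code_types(
    id = c("NTX", "PLS", "ANS", "MCS", "PLG", "ANG", "MCG", "CMG"),
    label = c("Non Taxonomic", "Plant species", "Animal species",
              "Microorganism species", "Plant taxonomic group",
              "Animal taxonomic group", "Microorganism taxonomic group",
              "Commodity group"),
    group = c("non_taxonomic", "plant", "animal", "microorganism",
              "plant_group", "animal_group", "microorganism_group", "commodity")
  )
}

exemplar_scheme <- function() {
  categorization_scheme(
    nodes = data.frame(
      id = c("QuarantineOrganism", "QuarantinePest"),
      parent = c(NA, "QuarantineOrganism"),
      stringsAsFactors = FALSE
    ),
    q_list_map = c("A1 list" = "QuarantinePest")
  )
}

#' The worked-example knowledge base
#'
#' Twelve codes: the winter soft wheat crop code TRZAW (part of the soft
#' wheat crops group 3SWHC, with a Danish synonym carrying axiom-annotated
#' metadata), the wheat taxon TRZAX under the genus code 1TRZG, the rice
#' leaf miner AGMYOR under 1AGMYG with a host relation to TRZAX and a
#' quarantine categorization, the brassica species BRSJU/BRSRW associated
#' with the crop groups 3LFBC/3MUSC, and the treatment-methods group 3TMETM
#' with its member 3BRUSM.
#'
#' @return an `eppo_kb`.
#' @export
exemplar_kb <- function() {
  d0 <- "2001-01-01"
  codes <- list(
    code_record("1TRZG", "taxonomic",
                name_record("Triticum", "la"),
                created = d0, code_type = "PLG",
                level_name = "Genus", level_distance = 0L),
    code_record("TRZAX", "taxonomic",
                name_record("Triticum aestivum", "la"),
                created = d0, parent = "1TRZG", code_type = "PLS",
                level_name = "Species", level_distance = 1L,
                associated_with = "TRZAW"),
    code_record("1AGMYG", "taxonomic",
                name_record("Agromyza", "la"),
                created = d0, code_type = "ANG",
                level_name = "Genus", level_distance = 0L),
    code_record("AGMYOR", "taxonomic",
                name_record("Agromyza oryzae", "la", authority = "Munakata"),
                created = d0, parent = "1AGMYG", code_type = "ANS",
                level_name = "Species", level_distance = 1L),
    code_record("BRSJU", "taxonomic",
                name_record("Brassica juncea", "la"),
                created = d0, code_type = "PLS",
                level_name = "Species", level_distance = 0L,
                associated_with = c("3LFBC", "3MUSC")),
    code_record("BRSRW", "taxonomic",
                name_record("Brassica rapa", "la"),
                created = d0, code_type = "PLS",
                level_name = "Species", level_distance = 0L,
                associated_with = "3LFBC"),
    code_record("TRZAW", "non_taxonomic",
                rbind(
                  name_record("Triticum aestivum (winter)", "la"),
                  name_record("soft wheat (winter)", "en", "alternative"),
                  name_record("vinterhvede", "da", "synonym",
                              created = "2002-02-02", active = TRUE),
                  name_record("Triticum aestivum", "la", "synonym")
                ),
                created = d0, modified = "2003-03-03", code_type = "NTX",
                part_of = "3SWHC"),
    code_record("3SWHC", "non_taxonomic",
                name_record("soft wheat crops", "en"),
                created = d0, code_type = "NTX"),
    code_record("3LFBC", "non_taxonomic",
                name_record("leafy brassica crops", "en"),
                created = d0, code_type = "NTX"),
    code_record("3MUSC", "non_taxonomic",
                name_record("mustard crops", "en"),
                created = d0, code_type = "NTX"),
    code_record("3TMETM", "non_taxonomic",
                name_record("treatment methods", "en"),
                created = d0, code_type = "NTX"),
    code_record("3BRUSM", "non_taxonomic",
                name_record("brushing", "en"),
                created = d0, code_type = "NTX", part_of = "3TMETM",
                comment = BRUSHING_COMMENT)
  )
  assemble_kb(
    codes = codes,
    relations = host_pest_relation("AGMYOR", "TRZAX", "host"),
    categorizations = categorization_status("AGMYOR", "A1 list",
                                            continent = "Europe",
                                            country = "Spain", iso_code = "ES",
                                            year_added = 2002L),
    replacements = empty_replacements(),
    scheme = exemplar_scheme(),
    levels = exemplar_levels(),
    types = exemplar_types()
  )
}

exemplar_lexicon_terms <- function() {
  data.frame(
    id = "NCBITaxon:4565",
    name = "Triticum aestivum",
    stringsAsFactors = FALSE
  )
}

write_obo <- function(terms, path, synonyms = NULL) {
  out <- c("format-version: 1.2", "ontology: taxonomy-lexicon", "")
  for (i in seq_len(nrow(terms))) {
    out <- c(out, "[Term]",
             paste0("id: ", terms$id[i]),
             paste0("name: ", terms$name[i]))
    if (!is.null(synonyms)) {
      syn <- synonyms[synonyms$id == terms$id[i], , drop = FALSE]
      for (j in seq_len(nrow(syn))) {
        out <- c(out, sprintf("synonym: \"%s\" EXACT []", syn$text[j]))
      }
    }
    out <- c(out, "")
  }
  write_text(paste(out, collapse = "\n"), path)
}

#' Write the worked-example bundle
#'
#' @param dir writable output directory (created if missing).
#' @param dialect code-table dialect to write.
#' @return an `eppo_source_bundle`.
#' @export
exemplar_bundle <- function(dir, dialect = c("csv", "sqlite")) {
  dialect <- match.arg(dialect)
  bundle <- write_bundle(exemplar_kb(), dir, dialect)
  write_obo(exemplar_lexicon_terms(), file.path(dir, "taxonomy.obo"))
  bundle
}

# ---- random bundles -------------------------------------------------------

#' Fixture specification for random bundle generation
#'
#' @param seed integer RNG seed; same spec, same bundle, byte for byte.
#' @param n_taxa number of taxonomic codes (forest of given depth).
#' @param max_depth maximum taxonomy depth (>= 1).
#' @param n_nontaxonomic number of non-taxonomic/commodity-group codes.
#' @param n_relations number of host-pest relations drawn.
#' @param n_categorizations number of categorization statuses drawn.
#' @param n_replacements number of replaced codes (chains, never cycles).
#' @param languages language tags used for generated common names.
#' @param include_exemplars also embed the worked-example records.
#' @param unmapped_q_fraction fraction of categorization rows whose q-list
#'   is deliberately left out of the scheme map (maintenance warning path).
#' @param lexicon_fraction fraction of taxonomic preferred names duplicated
#'   into the companion OBO lexicon so enrichment is guaranteed hits.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_taxa = 100L, max_depth = 6L,
                         n_nontaxonomic = 20L, n_relations = 30L,
                         n_categorizations = 20L, n_replacements = 10L,
                         languages = c("en", "fr", "de", "da"),
                         include_exemplars = FALSE,
                         unmapped_q_fraction = 0.2,
                         lexicon_fraction = 0.5) {
  stopifnot(max_depth >= 1L, n_taxa >= 0L, n_nontaxonomic >= 0L,
            n_relations >= 0L, n_categorizations >= 0L, n_replacements >= 0L)
  structure(list(
    seed = as.integer(seed), n_taxa = as.integer(n_taxa),
    max_depth = as.integer(max_depth),
    n_nontaxonomic = as.integer(n_nontaxonomic),
    n_relations = as.integer(n_relations),
    n_categorizations = as.integer(n_categorizations),
    n_replacements = as.integer(n_replacements),
    languages = as.character(languages),
    include_exemplars = isTRUE(include_exemplars),
    unmapped_q_fraction = unmapped_q_fraction,
    lexicon_fraction = lexicon_fraction
  ), class = "fixture_spec")
}

RANDOM_LEVELS <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus",
                   "Species")
RELATION_CATEGORIES <- c("host", "major", "minor", "alternate", "wild_weed",
                         "incidental", "experimental")

# pronounceable Latin-like binomials built from syllable bigrams
latin_word <- function(n_syl) {
  consonants <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vowels <- c("a", "e", "i", "o", "u")
  paste(vapply(seq_len(n_syl), function(i) {
    paste0(sample(consonants, 1L), sample(vowels, 1L))
  }, ""), collapse = "")
}

latin_name <- function(two_part = TRUE) {
  genus <- latin_word(sample(2:4, 1L))
  substr(genus, 1L, 1L) <- toupper(substr(genus, 1L, 1L))
  if (!two_part) return(genus)
  paste(genus, latin_word(sample(2:4, 1L)))
}

random_code <- function(existing, prefix_digit = FALSE) {
  repeat {
    code <- if (prefix_digit) {
      paste0(sample(1:9, 1L), paste(sample(LETTERS, 4L, replace = TRUE), collapse = ""))
    } else {
      paste(sample(LETTERS, 5L, replace = TRUE), collapse = "")
    }
    if (!code %in% existing) return(code)
  }
}

random_date <- function(from = 1990L, to = 2020L) {
  sprintf("%04d-%02d-%02d", sample(from:to, 1L), sample(1:12, 1L), sample(1:28, 1L))
}

random_scheme <- function() {
  categorization_scheme(
    nodes = data.frame(
      id = c("QuarantineOrganism", "QuarantinePest",
             "RegulatedNonQuarantinePest", "AlertListOrganism"),
      parent = c(NA, "QuarantineOrganism", "QuarantineOrganism", NA),
      stringsAsFactors = FALSE
    ),
    q_list_map = c("A1 list" = "QuarantinePest",
                   "A2 list" = "QuarantinePest",
                   "RNQP" = "RegulatedNonQuarantinePest",
                   "Alert list" = "AlertListOrganism")
  )
}

#' Generate a seeded random knowledge base
#'
#' Same spec, same KB. The generator's bookkeeping (taxa duplicated into the
#' lexicon, deliberately unmapped q-lists) is attached as attribute `meta`.
#'
#' @param spec a [fixture_spec()].
#' @return an `eppo_kb` with attribute `meta`.
#' @export
random_kb <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  base_kb <- if (spec$include_exemplars) exemplar_kb() else NULL
  existing <- if (is.null(base_kb)) character(0) else names(base_kb$codes)

  codes <- list()
  taxa <- character(0)
  depth <- integer(0)

  species_types <- c("PLS", "ANS", "MCS")
  group_types <- c("PLG", "ANG", "MCG")

  for (i in seq_len(spec$n_taxa)) {
    code <- random_code(c(existing, taxa))
    d <- 0L
    parent <- NA_character_
    attachable <- taxa[depth < spec$max_depth - 1L]
    if (length(attachable) > 0L && stats::runif(1L) < 0.8) {
      parent <- sample(attachable, 1L)
      d <- depth[match(parent, taxa)] + 1L
    }
    level <- RANDOM_LEVELS[min(d + 1L, length(RANDOM_LEVELS))]
    is_species <- level == "Species" || stats::runif(1L) < 0.2
    nms <- list(name_record(latin_name(is_species), "la",
                            authority = if (stats::runif(1L) < 0.3) {
                              latin_name(FALSE)
                            } else NA))
    for (lang in spec$languages) {
      if (stats::runif(1L) < 0.4) {
        nms[[length(nms) + 1L]] <- name_record(
          latin_word(sample(2:4, 1L)), lang,
          role = sample(c("alternative", "synonym"), 1L),
          created = if (stats::runif(1L) < 0.5) random_date() else NA,
          active = TRUE
        )
      }
    }
    # inactive names always carry a creation date so the flag is reified
    if (stats::runif(1L) < 0.2) {
      nms[[length(nms) + 1L]] <- name_record(latin_word(3L), "la", "synonym",
                                             created = random_date(),
                                             active = FALSE)
    }
    codes[[length(codes) + 1L]] <- code_record(
      code = code, kind = "taxonomic", names = do.call(rbind, nms),
      created = random_date(), modified = if (stats::runif(1L) < 0.3) random_date() else NA,
      active = TRUE, parent = parent,
      code_type = if (is_species) sample(species_types, 1L) else sample(group_types, 1L),
      level_name = level, level_distance = d
    )
    taxa <- c(taxa, code)
    depth <- c(depth, d)
  }

  nt_codes <- character(0)
  nt_kind <- character(0)
  for (i in seq_len(spec$n_nontaxonomic)) {
    code <- random_code(c(existing, taxa, nt_codes), prefix_digit = TRUE)
    kind <- if (stats::runif(1L) < 0.3) "commodity_group" else "non_taxonomic"
    part_of <- if (length(nt_codes) > 0L && stats::runif(1L) < 0.5) {
      sample(nt_codes, 1L)
    } else character(0)
    codes[[length(codes) + 1L]] <- code_record(
      code = code, kind = kind,
      names = name_record(paste(latin_word(3L), "crops"), "en"),
      created = random_date(), active = TRUE,
      code_type = if (kind == "commodity_group") "CMG" else "NTX",
      part_of = part_of,
      comment = if (stats::runif(1L) < 0.3) {
        paste("Synthetic definition of group", code)
      } else NA
    )
    nt_codes <- c(nt_codes, code)
    nt_kind <- c(nt_kind, kind)
  }

  # associations: taxa or groups -> group codes
  if (length(nt_codes) > 0L) {
    for (k in seq_along(codes)) {
      r <- codes[[k]]
      if (stats::runif(1L) < 0.2) {
        targets <- setdiff(sample(nt_codes, min(2L, length(nt_codes))), r$code)
        if (length(targets) > 0L) {
          codes[[k]] <- code_record(
            r$code, r$kind, r$names, r$created, r$modified, r$active, r$parent,
            r$code_type, r$level_name, r$level_distance, r$part_of,
            associated_with = unique(c(r$associated_with, targets)),
            comment = r$comment
          )
        }
      }
    }
  }

  # replaced codes: inactive extra taxa forming chains, never cycles
  replaced <- character(0)
  replacements <- list()
  for (i in seq_len(spec$n_replacements)) {
    code <- random_code(c(existing, taxa, nt_codes, replaced))
    codes[[length(codes) + 1L]] <- code_record(
      code = code, kind = "taxonomic",
      names = name_record(latin_name(), "la"),
      created = random_date(), active = FALSE,
      code_type = "PLS", level_name = "Species", level_distance = 0L
    )
    replaced <- c(replaced, code)
  }
  for (i in seq_along(replaced)) {
    target <- if (i < length(replaced) && stats::runif(1L) < 0.3) {
      replaced[i + 1L]
    } else if (length(taxa) > 0L) {
      sample(taxa, 1L)
    } else {
      next
    }
    replacements[[length(replacements) + 1L]] <- replacement_record(
      replaced[i], target,
      date = if (stats::runif(1L) < 0.6) random_date(2000L, 2020L) else NA
    )
  }

  # host-pest relations among live taxa
  relations <- list()
  if (length(taxa) >= 2L) {
    for (i in seq_len(spec$n_relations)) {
      pair <- sample(taxa, 2L)
      relations[[length(relations) + 1L]] <- host_pest_relation(
        pair[1L], pair[2L], sample(RELATION_CATEGORIES, 1L)
      )
    }
  }

  scheme <- random_scheme()
  mapped_q <- names(scheme$q_list_map)
  unmapped_pool <- paste("Lista", c("X1", "X2", "X3"))
  categorizations <- list()
  used_unmapped <- character(0)
  if (length(taxa) > 0L) {
    for (i in seq_len(spec$n_categorizations)) {
      use_unmapped <- stats::runif(1L) < spec$unmapped_q_fraction
      ql <- if (use_unmapped) sample(unmapped_pool, 1L) else sample(mapped_q, 1L)
      if (use_unmapped) used_unmapped <- union(used_unmapped, ql)
      ya <- sample(1990:2015, 1L)
      categorizations[[length(categorizations) + 1L]] <- categorization_status(
        subject = sample(taxa, 1L), q_list = ql,
        continent = "Europe",
        country = sample(c("Spain", "France", "Germany", "Italy"), 1L),
        iso_code = sample(c("ES", "FR", "DE", "IT", NA), 1L),
        year_added = ya,
        year_deleted = if (stats::runif(1L) < 0.2) ya + sample(1:5, 1L) else NA,
        year_trans = if (stats::runif(1L) < 0.1) ya + sample(1:5, 1L) else NA
      )
    }
  }

  # companion lexicon bookkeeping: a fraction of taxa mirrored by name
  lex <- list()
  for (i in seq_along(taxa)) {
    if (stats::runif(1L) < spec$lexicon_fraction) {
      r <- codes[[i]]
      lex[[length(lex) + 1L]] <- data.frame(
        id = sprintf("NCBITaxon:%d", 100000L + i),
        name = r$names$text[r$names$role == "preferred"][1L],
        code = r$code,
        stringsAsFactors = FALSE
      )
    }
  }
  lex_df <- if (length(lex) == 0L) {
    data.frame(id = character(), name = character(), code = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lex)
  }
  # a few decoy terms that match nothing
  for (i in seq_len(3L)) {
    lex_df <- rbind(lex_df, data.frame(
      id = sprintf("NCBITaxon:%d", 900000L + i),
      name = paste("Decoyus", latin_word(3L)),
      code = NA_character_, stringsAsFactors = FALSE
    ))
  }

  all_codes <- codes
  rels <- if (length(relations) == 0L) empty_relations() else {
    unique(do.call(rbind, relations))
  }
  cats <- if (length(categorizations) == 0L) empty_categorizations() else {
    do.call(rbind, categorizations)
  }
  reps <- if (length(replacements) == 0L) empty_replacements() else {
    do.call(rbind, replacements)
  }
  if (spec$include_exemplars) {
    all_codes <- c(base_kb$codes, all_codes)
    rels <- rbind(base_kb$relations, rels)
    cats <- rbind(base_kb$categorizations, cats)
    reps <- rbind(base_kb$replacements, reps)
    scheme <- random_scheme()
  }
  kb <- assemble_kb(
    codes = all_codes, relations = rels, categorizations = cats,
    replacements = reps, scheme = scheme,
    levels = taxonomy_levels(RANDOM_LEVELS,
                             paste0("NCBITaxon:", tolower(RANDOM_LEVELS))),
    types = exemplar_types()
  )
  attr(kb, "meta") <- list(
    unmapped_q_lists = sort(used_unmapped),
    lexicon = lex_df,
    replaced = replaced
  )
  kb
}

#' Write a seeded random bundle
#'
#' @param spec a [fixture_spec()].
#' @param dir writable output directory.
#' @param dialect code-table dialect.
#' @return an `eppo_source_bundle` with the generator's `meta` attached.
#' @export
random_bundle <- function(spec, dir, dialect = c("csv", "sqlite")) {
  dialect <- match.arg(dialect)
  kb <- random_kb(spec)
  meta <- attr(kb, "meta")
  bundle <- write_bundle(kb, dir, dialect)
  write_obo(meta$lexicon[, c("id", "name")], file.path(dir, "taxonomy.obo"))
  bundle$meta <- meta
  bundle
}

# ---- bundle writer --------------------------------------------------------

#' Serialize a knowledge base back to the canonical source layout
#'
#' Inverse of [read_bundle()]: writes the code table (CSV tables or a SQLite
#' database), the replaced-codes CSV, the categorization CSV, the relations
#' JSON and the scheme/config YAML, so that `read_bundle(write_bundle(kb))`
#' reproduces the KB exactly.
#'
#' @param kb an `eppo_kb`.
#' @param dir output directory (created if missing).
#' @param dialect `"csv"` or `"sqlite"`.
#' @param ontology_config optional ontology-header metadata stored in the
#'   config YAML.
#' @return an `eppo_source_bundle`.
#' @export
write_bundle <- function(kb, dir, dialect = c("csv", "sqlite"),
                         ontology_config = NULL) {
  stopifnot(inherits(kb, "eppo_kb"))
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  codes_df <- do.call(rbind, lapply(kb$codes, function(r) {
    data.frame(
      code = r$code, kind = r$kind, created = r$created,
      modified = r$modified %||% NA_character_,
      active = tolower(as.character(r$active)), parent = r$parent,
      code_type = r$code_type, level_name = r$level_name,
      level_distance = if (is.na(r$level_distance)) NA_character_ else {
        as.character(r$level_distance)
      },
      comment = r$comment, stringsAsFactors = FALSE
    )
  })) %||% data.frame()
  if (is.null(codes_df) || nrow(codes_df) == 0L) {
    codes_df <- stats::setNames(
      as.data.frame(matrix(character(0), 0L, length(CODES_COLUMNS))), CODES_COLUMNS)
  }

  names_df <- do.call(rbind, lapply(kb$codes, function(r) {
    cbind(data.frame(code = rep(r$code, nrow(r$names)), stringsAsFactors = FALSE),
          r$names)
  }))
  if (is.null(names_df)) {
    names_df <- stats::setNames(
      as.data.frame(matrix(character(0), 0L, length(NAMES_COLUMNS))), NAMES_COLUMNS)
  } else {
    names_df$active <- tolower(as.character(names_df$active))
    names_df <- names_df[, NAMES_COLUMNS, drop = FALSE]
  }

  links_df <- do.call(rbind, lapply(kb$codes, function(r) {
    rbind(
      if (length(r$part_of) > 0L) {
        data.frame(code = r$code, link_kind = "part_of", target = r$part_of,
                   stringsAsFactors = FALSE)
      },
      if (length(r$associated_with) > 0L) {
        data.frame(code = r$code, link_kind = "associated_with",
                   target = r$associated_with, stringsAsFactors = FALSE)
      }
    )
  }))
  if (is.null(links_df)) {
    links_df <- stats::setNames(
      as.data.frame(matrix(character(0), 0L, length(LINKS_COLUMNS))), LINKS_COLUMNS)
  }

  write_table <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE,
                     na = "", fileEncoding = "UTF-8", quote = TRUE)
  }

  if (dialect == "sqlite") {
    tmp <- tempfile("sqlite_src_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    for (spec_tab in list(list(codes_df, "codes"), list(names_df, "names"),
                          list(links_df, "links"))) {
      utils::write.csv(spec_tab[[1L]], file.path(tmp, paste0(spec_tab[[2L]], ".csv")),
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    }
    sqlite_load_csv(file.path(dir, "codes.sqlite"), tmp,
                    c("codes", "names", "links"))
  } else {
    write_table(codes_df, "codes")
    write_table(names_df, "names")
    write_table(links_df, "links")
  }

  write_table(kb$replacements, "replaced")
  cats <- kb$categorizations
  names(cats)[names(cats) == "subject"] <- "code"
  write_table(cats, "categorizations")

  rel_json <- jsonlite::toJSON(kb$relations, dataframe = "rows", pretty = TRUE,
                               na = "null")
  write_text(paste0(rel_json, "\n"), file.path(dir, "relations.json"))

  cfg <- list(
    categorizations = lapply(seq_len(nrow(kb$scheme$nodes)), function(i) {
      node <- list(id = kb$scheme$nodes$id[i])
      if (!is.na(kb$scheme$nodes$parent[i])) node$parent <- kb$scheme$nodes$parent[i]
      node
    }),
    q_lists = as.list(kb$scheme$q_list_map),
    levels = lapply(seq_len(nrow(kb$levels)), function(i) {
      lv <- list(id = kb$levels$id[i])
      if (!is.na(kb$levels$external_xref[i])) lv$xref <- kb$levels$external_xref[i]
      lv
    }),
    types = lapply(seq_len(nrow(kb$types)), function(i) {
      list(id = kb$types$id[i], label = kb$types$label[i], group = kb$types$group[i])
    }),
    ontology = as.list(ontology_config %||% default_ontology_config())
  )
  yaml_text <- yaml::as.yaml(cfg)
  write_text(yaml_text, file.path(dir, "scheme.yaml"))

  locate_bundle(dir)
}
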