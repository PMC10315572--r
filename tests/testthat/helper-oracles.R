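# Independent oracles used by the property tests. These re-derive expected
# quantities from first principles (graph walks, brute-force cross joins,
# per-record triple budgets) without calling the code paths they check.

# depth of a code obtained by a plain parent walk over the raw records
oracle_depth <- function(kb, code) {
  d <- 0L
  cur <- kb$codes[[code]]$parent
  seen <- character(0)
  while (!is.na(cur)) {
    if (cur %in% seen) stop("cycle")
    seen <- c(seen, cur)
    d <- d + 1L
    cur <- if (cur %in% names(kb$codes)) kb$codes[[cur]]$parent else NA_character_
  }
  d
}

# brute-force ancestor check: is `anc` an ancestor of `code`?
oracle_is_ancestor <- function(kb, code, anc) {
  cur <- kb$codes[[code]]$parent
  n <- 0L
  while (!is.na(cur) && n <= length(kb$codes)) {
    if (cur == anc) return(TRUE)
    cur <- if (cur %in% names(kb$codes)) kb$codes[[cur]]$parent else NA_character_
    n <- n + 1L
  }
  FALSE
}

# independently coded per-record triple budget for build_graph output;
# assumes no identifier collisions between scheme nodes / levels / types and
# no duplicate name rows (both guaranteed by the fixture generators)
oracle_triple_budget <- function(kb) {
  n <- 0L
  present <- function(x) sum(!is.na(x))
  # ontology header: owl:Ontology + title/creator/license/versionInfo
  n <- n + 5L
  # schema classes: declaration + label each, 3 kind subclass axioms
  n <- n + 8L * 2L + 3L
  n <- n + 3L * nrow(kb$scheme$nodes)
  n <- n + 3L * nrow(kb$levels) + present(kb$levels$external_xref)
  n <- n + 4L * nrow(kb$types)
  # core object properties + has_pest/has_host inverse pair
  n <- n + 8L + 2L
  n <- n + 6L * length(kb$categories)
  n <- n + 1L                      # has_taxonomy_level declaration
  n <- n + 16L                     # declared annotation properties
  replaced <- unique(kb$replacements$old_code)
  for (r in kb$codes) {
    n <- n + 5L                    # type, subclass, identifier, created, isActive
    if (!is.na(r$modified)) n <- n + 1L
    if (!is.na(r$comment)) n <- n + 1L
    if (!is.na(r$code_type)) n <- n + 1L
    if (r$kind == "taxonomic") {
      if (!is.na(r$level_name)) n <- n + 1L
      if (!is.na(r$level_distance)) n <- n + 1L
    }
    n <- n + length(r$part_of) + length(r$associated_with)
    n <- n + nrow(r$names)
    for (j in seq_len(nrow(r$names))) {
      nm <- r$names[j, ]
      if (!is.na(nm$created) || !is.na(nm$modified) || !is.na(nm$authority) ||
          !nm$active) {
        n <- n + 4L + 1L + present(c(nm$created, nm$modified, nm$authority))
      }
    }
    if (r$code %in% replaced) n <- n + 1L  # owl:deprecated
  }
  for (i in seq_len(nrow(kb$replacements))) {
    n <- n + 1L                    # termReplacedBy
    if (!is.na(kb$replacements$date[i])) n <- n + 5L
  }
  n <- n + 2L * nrow(kb$relations)
  mapped <- names(kb$scheme$q_list_map)
  for (i in seq_len(nrow(kb$categorizations))) {
    st <- kb$categorizations[i, ]
    n <- n + 2L + 1L + 1L          # type, subclass, q_list, subject link
    if (st$q_list %in% mapped) n <- n + 1L
    n <- n + present(c(st$continent, st$country, st$iso_code))
    n <- n + present(c(st$year_added, st$year_deleted, st$year_trans))
  }
  n
}

# brute-force lexical cross join between a KB's names and an OBO lexicon file
oracle_expected_mappings <- function(kb, obo_path) {
  lines <- readLines(obo_path, encoding = "UTF-8")
  ids <- character(0); lexemes <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "[Term]") {
      cur <- length(ids) + 1L
      lexemes[cur] <- list(character(0))
      next
    }
    if (startsWith(ln, "id: ")) ids[cur] <- substring(ln, 5L)
    if (startsWith(ln, "name: ")) {
      lexemes[[cur]] <- c(lexemes[[cur]], substring(ln, 7L))
    }
    if (startsWith(ln, "synonym: ")) {
      m <- regmatches(ln, regexec('^synonym: "([^"]*)" EXACT', ln))[[1L]]
      if (length(m) == 2L) lexemes[[cur]] <- c(lexemes[[cur]], m[2L])
    }
  }
  out <- list()
  for (code in names(kb$codes)) {
    texts <- normalize_label(kb$codes[[code]]$names$text)
    for (t in seq_along(ids)) {
      if (any(normalize_label(lexemes[[t]]) %in% texts)) {
        iri <- paste0("http://purl.obolibrary.org/obo/",
                      gsub(":", "_", ids[t], fixed = TRUE))
        out[[length(out) + 1L]] <- c(code = code, taxon_iri = iri)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(code = character(), taxon_iri = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE))
  df <- df[order(df$code, df$taxon_iri), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# independent Turtle/OWL conformance + isomorphism oracle via python rdflib
rdflib_oracle <- function(ttl_path, rdfxml_path = NULL) {
  code <- paste(
    "import sys, rdflib",
    "from rdflib.compare import isomorphic",
    "g1 = rdflib.Graph(); g1.parse(sys.argv[1], format='turtle')",
    "if len(sys.argv) > 2:",
    "    g2 = rdflib.Graph(); g2.parse(sys.argv[2], format='xml')",
    "    print(len(g1), len(g2), isomorphic(g1, g2))",
    "else:",
    "    print(len(g1))",
    sep = "\n")
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  args <- c(script, ttl_path, rdfxml_path)
  out <- suppressWarnings(system2("python", args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(ok = is.null(status) || status == 0L, output = out)
}
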