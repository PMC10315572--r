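#' @title Lexical enrichment with an external taxonomy
#'
#' @description
#' Matches code annotations (preferred names, alternative names, exact
#' synonyms) against the term names and exact synonyms of an external
#' taxonomy lexicon in OBO format (NCBITaxon-style) and injects
#' `oboInOwl:hasDbXref` cross-references into the emitted ontology graph.
#' Matching is exact on normalized strings (casefolded, whitespace-collapsed,
#' surrounding punctuation stripped); no fuzzy alignment is attempted, which
#' keeps every injected cross-reference re-derivable.
#'
#' @name taxonomy_enrich
NULL

#' Normalize a label for lexical matching
#'
#' Casefolds, collapses internal whitespace to single spaces and strips
#' surrounding punctuation/whitespace. Idempotent.
#'
#' @param text character vector.
#' @return normalized character vector.
#' @export
normalize_label <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x
}

obo_iri_from_id <- function(id) {
  paste0("http://purl.obolibrary.org/obo/", gsub(":", "_", id, fixed = TRUE))
}

#' Parse an OBO lexicon into a taxon index
#'
#' Reads `[Term]` stanzas (`id:`, `name:`, `synonym: "..." EXACT`) and
#' indexes every term name and exact synonym under its normalized form.
#' Identifiers of the form `PREFIX:1234` are turned into OBO PURLs
#' (`.../obo/PREFIX_1234`).
#'
#' @param obo_path path to an OBO flat file.
#' @return object of class `eppo_taxon_index`: a multimap from normalized
#'   lexeme to data frames of `(taxon_iri, field)` where field is `name` or
#'   `synonym`.
#' @export
build_taxon_index <- function(obo_path) {
  lines <- strsplit(read_text(obo_path), "\n", fixed = TRUE)[[1L]]
  lines <- sub("\\s+$", "", lines)
  starts <- which(lines == "[Term]")
  index <- new.env(parent = emptyenv())
  n_terms <- 0L
  add <- function(lexeme, iri, field) {
    if (!nzchar(lexeme)) return(invisible())
    cur <- if (exists(lexeme, envir = index, inherits = FALSE)) {
      get(lexeme, envir = index)
    } else {
      data.frame(taxon_iri = character(), field = character(), stringsAsFactors = FALSE)
    }
    assign(lexeme, rbind(cur, data.frame(taxon_iri = iri, field = field,
                                         stringsAsFactors = FALSE)),
           envir = index)
  }
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    get_field <- function(key) {
      hits <- chunk[startsWith(chunk, paste0(key, ":"))]
      sub("^\\s*", "", substring(hits, nchar(key) + 2L))
    }
    id <- get_field("id")
    if (length(id) == 0L || !nzchar(id[1L])) {
      eppo_abort(sprintf("OBO term stanza %d has no id", k), "eppo_parse_error")
    }
    nm <- get_field("name")
    if (length(nm) == 0L) {
      eppo_abort(sprintf("OBO term stanza '%s' has no name", id[1L]), "eppo_parse_error")
    }
    iri <- obo_iri_from_id(id[1L])
    n_terms <- n_terms + 1L
    add(normalize_label(nm[1L]), iri, "name")
    for (syn in get_field("synonym")) {
      m <- regmatches(syn, regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"\\s+EXACT\\b", syn))[[1L]]
      if (length(m) == 2L) {
        add(normalize_label(gsub("\\\\(.)", "\\1", m[2L])), iri, "synonym")
      }
    }
  }
  structure(list(index = index, n_terms = n_terms), class = "eppo_taxon_index")
}

#' @export
print.eppo_taxon_index <- function(x, ...) {
  cat(sprintf("<eppo_taxon_index: %d terms, %d lexemes>\n",
              x$n_terms, length(ls(x$index))))
  invisible(x)
}

taxon_lookup <- function(index, lexeme) {
  if (exists(lexeme, envir = index$index, inherits = FALSE)) {
    get(lexeme, envir = index$index)
  } else {
    NULL
  }
}

#' Match code annotations against a taxon index
#'
#' Each code's preferred name, alternative names and exact synonyms are
#' normalized and looked up in the index; every distinct (code, taxon) hit
#' yields one mapping record. Codes hitting more than one distinct taxon
#' have all of their records flagged ambiguous. Ordering is deterministic
#' (code, then taxon IRI).
#'
#' @param kb an `eppo_kb`.
#' @param index an `eppo_taxon_index` from [build_taxon_index()].
#' @return data frame with columns `code`, `matched_text`, `taxon_iri`,
#'   `ambiguous`.
#' @export
match_annotations <- function(kb, index) {
  stopifnot(inherits(kb, "eppo_kb"), inherits(index, "eppo_taxon_index"))
  rows <- list()
  for (code in names(kb$codes)) {
    r <- kb$codes[[code]]
    hits <- list()
    for (j in seq_len(nrow(r$names))) {
      text <- r$names$text[j]
      found <- taxon_lookup(index, normalize_label(text))
      if (is.null(found)) next
      for (iri in unique(found$taxon_iri)) {
        if (is.null(hits[[iri]])) hits[[iri]] <- text
      }
    }
    if (length(hits) == 0L) next
    iris <- sort(names(hits))
    rows[[length(rows) + 1L]] <- data.frame(
      code = code,
      matched_text = unname(unlist(hits[iris])),
      taxon_iri = iris,
      ambiguous = length(iris) > 1L,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(code = character(), matched_text = character(),
                      taxon_iri = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[stable_order(out$code, out$taxon_iri), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inject cross-references into an emitted graph
#'
#' Each admitted mapping adds one `oboInOwl:hasDbXref` triple on the code
#' class. Enrichment is monotone: no existing triple is removed or altered.
#'
#' @param graph an [rdf_graph] from [build_graph()].
#' @param mappings data frame from [match_annotations()].
#' @param policy `"all"` (emit every exact hit; multi-hits stay flagged in
#'   the report) or `"unambiguous_only"`.
#' @param base_iri ontology namespace of the code classes.
#' @return list with elements `graph` (enriched) and `report` (counts of
#'   `added`, `skipped_ambiguous`, `unmatched_codes`).
#' @export
apply_mappings <- function(graph, mappings, policy = c("all", "unambiguous_only"),
                           base_iri = EPPO_BASE_IRI) {
  policy <- match.arg(policy)
  admitted <- if (policy == "all") mappings else mappings[!mappings$ambiguous, , drop = FALSE]
  skipped <- nrow(mappings) - nrow(admitted)

  df <- graph$triples
  code_subjects <- df$s[df$p == IRI$dc_identifier & df$o_kind == "lit" &
                          df$s == paste0(base_iri, df$o) & is_eppo_code(df$o)]
  code_subjects <- unique(code_subjects)

  if (nrow(admitted) > 0L) {
    subj <- paste0(base_iri, admitted$code)
    absent <- !(subj %in% code_subjects)
    if (any(absent)) {
      eppo_abort(sprintf("mapping subject %s is not a code class in the graph",
                         subj[absent][1L]), "eppo_application_error")
    }
    graph <- rdf_add(graph, subj, IRI$db_xref, admitted$taxon_iri, "iri")
  }
  matched_codes <- unique(mappings$code)
  report <- list(
    added = nrow(admitted),
    skipped_ambiguous = skipped,
    unmatched_codes = length(code_subjects) - sum(paste0(base_iri, matched_codes)
                                                  %in% code_subjects)
  )
  list(graph = graph, report = report)
}

#' One-step enrichment of an emitted graph
#'
#' Convenience wrapper: build the taxon index from an OBO lexicon, match the
#' KB's annotations and inject the cross-references.
#'
#' @param graph emitted [rdf_graph].
#' @param kb the `eppo_kb` the graph was built from.
#' @param obo_path OBO lexicon path.
#' @inheritParams apply_mappings
#' @return list with `graph`, `report` and the `mappings` data frame.
#' @export
enrich_graph <- function(graph, kb, obo_path, policy = "all",
                         base_iri = EPPO_BASE_IRI) {
  index <- build_taxon_index(obo_path)
  mappings <- match_annotations(kb, index)
  res <- apply_mappings(graph, mappings, policy, base_iri)
  res$mappings <- mappings
  res
}
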