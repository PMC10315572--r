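#' @title In-memory RDF triple store
#'
#' @description
#' A minimal, deterministic RDF graph: a data frame of triples plus a prefix
#' map. Objects are tagged with a kind (`iri`, `bnode`, `lit`) and literals may
#' carry a language tag or a datatype IRI (never both). The store is the
#' substrate for the OWL emitter, the Turtle reader/writer and the SPARQL
#' engine; it is intentionally plain so that equality, diffing and sorting are
#' exact set operations on rows.
#'
#' @name rdf_graph
NULL

default_prefixes <- function() {
  c(
    rdf      = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs     = "http://www.w3.org/2000/01/rdf-schema#",
    owl      = "http://www.w3.org/2002/07/owl#",
    xsd      = "http://www.w3.org/2001/XMLSchema#",
    skos     = "http://www.w3.org/2004/02/skos/core#",
    dc       = "http://purl.org/dc/elements/1.1/",
    dcterms  = "http://purl.org/dc/terms/",
    oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
    obo      = "http://purl.obolibrary.org/obo/",
    sio      = "http://semanticscience.org/resource/"
  )
}

empty_triples <- function() {
  data.frame(
    s = character(), p = character(), o = character(),
    o_kind = character(), lang = character(), dtype = character(),
    stringsAsFactors = FALSE
  )
}

#' Create an empty RDF graph
#'
#' @param prefixes named character vector mapping prefix labels to namespace
#'   IRIs. The defaults cover the vocabularies the emitter uses.
#' @return an object of class `rdf_graph`.
#' @export
rdf_graph <- function(prefixes = default_prefixes()) {
  structure(
    list(triples = empty_triples(), prefixes = prefixes),
    class = "rdf_graph"
  )
}

#' Add triples to a graph
#'
#' Vectorized over all arguments. Duplicate triples are silently collapsed
#' (RDF graphs are sets).
#'
#' @param graph an `rdf_graph`.
#' @param s,p subject / predicate IRIs (subjects may be blank-node labels
#'   written `_:label`).
#' @param o object: IRI, blank-node label, or literal lexical form.
#' @param o_kind one of `"iri"`, `"bnode"`, `"lit"`.
#' @param lang literal language tag or `NA`.
#' @param dtype literal datatype IRI or `NA`.
#' @return the updated graph.
#' @export
rdf_add <- function(graph, s, p, o, o_kind = "iri", lang = NA_character_,
                    dtype = NA_character_) {
  stopifnot(inherits(graph, "rdf_graph"))
  n <- max(length(s), length(p), length(o))
  add <- data.frame(
    s = rep_len(as.character(s), n), p = rep_len(as.character(p), n),
    o = rep_len(as.character(o), n),
    o_kind = rep_len(as.character(o_kind), n),
    lang = rep_len(as.character(lang), n),
    dtype = rep_len(as.character(dtype), n),
    stringsAsFactors = FALSE
  )
  graph$triples <- rbind(graph$triples, add)
  graph$triples <- graph$triples[!duplicated(triple_keys(graph$triples)), , drop = FALSE]
  rownames(graph$triples) <- NULL
  graph
}

rdf_from_triples <- function(df, prefixes = default_prefixes()) {
  g <- rdf_graph(prefixes)
  df <- df[!duplicated(triple_keys(df)), , drop = FALSE]
  rownames(df) <- NULL
  g$triples <- df
  g
}

# One canonical string per triple; used for set semantics and sorting.
triple_keys <- function(df) {
  paste(df$s, df$p, df$o, df$o_kind,
        ifelse(is.na(df$lang), "", df$lang),
        ifelse(is.na(df$dtype), "", df$dtype),
        sep = "\r")
}

#' Number of triples in a graph
#' @param graph an `rdf_graph`.
#' @return integer count.
#' @export
rdf_size <- function(graph) nrow(graph$triples)

#' Test whether a graph contains matching triples
#'
#' `NA` arguments act as wildcards. Literal matches compare the lexical form
#' only unless `lang`/`dtype` are given.
#'
#' @inheritParams rdf_add
#' @return `TRUE` if at least one triple matches.
#' @export
rdf_has <- function(graph, s = NA, p = NA, o = NA, o_kind = NA, lang = NA,
                    dtype = NA) {
  nrow(rdf_match(graph, s, p, o, o_kind, lang, dtype)) > 0L
}

rdf_match <- function(graph, s = NA, p = NA, o = NA, o_kind = NA, lang = NA,
                      dtype = NA) {
  df <- graph$triples
  keep <- rep(TRUE, nrow(df))
  if (!is.na(s)) keep <- keep & df$s == s
  if (!is.na(p)) keep <- keep & df$p == p
  if (!is.na(o)) keep <- keep & df$o == o
  if (!is.na(o_kind)) keep <- keep & df$o_kind == o_kind
  if (!is.na(lang)) keep <- keep & !is.na(df$lang) & df$lang == lang
  if (!is.na(dtype)) keep <- keep & !is.na(df$dtype) & df$dtype == dtype
  df[keep, , drop = FALSE]
}

#' Set equality of two graphs
#'
#' Compares the triple sets exactly (blank-node labels included). For
#' label-insensitive comparison use an isomorphism checker.
#'
#' @param a,b `rdf_graph` objects.
#' @return logical.
#' @export
rdf_equal <- function(a, b) {
  setequal(triple_keys(a$triples), triple_keys(b$triples))
}

#' Triple-level difference of two graphs
#'
#' @param a,b `rdf_graph` objects.
#' @return list with data frames `only_a` and `only_b`.
#' @export
rdf_diff <- function(a, b) {
  ka <- triple_keys(a$triples)
  kb <- triple_keys(b$triples)
  list(
    only_a = a$triples[!(ka %in% kb), , drop = FALSE],
    only_b = b$triples[!(kb %in% ka), , drop = FALSE]
  )
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triples, %d prefixes>\n",
              nrow(x$triples), length(x$prefixes)))
  invisible(x)
}

# Mutable triple accumulator: building large graphs by repeated rbind is
# quadratic, so the emitter collects blocks in a list and binds once.
triple_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$blocks <- list()
  env$n <- 0L
  env
}

tb_add <- function(tb, s, p, o, o_kind = "iri", lang = NA_character_,
                   dtype = NA_character_) {
  n <- max(length(s), length(p), length(o))
  if (n == 0L) return(invisible(tb))
  tb$n <- tb$n + 1L
  tb$blocks[[tb$n]] <- data.frame(
    s = rep_len(as.character(s), n), p = rep_len(as.character(p), n),
    o = rep_len(as.character(o), n),
    o_kind = rep_len(as.character(o_kind), n),
    lang = rep_len(as.character(lang), n),
    dtype = rep_len(as.character(dtype), n),
    stringsAsFactors = FALSE
  )
  invisible(tb)
}

tb_graph <- function(tb, prefixes = default_prefixes()) {
  if (tb$n == 0L) return(rdf_graph(prefixes))
  rdf_from_triples(do.call(rbind, tb$blocks), prefixes)
}
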