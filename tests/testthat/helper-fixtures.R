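# Shared fixtures, built once per test run to keep the suite fast. Everything
# is generated in-code; nothing binary ships with the package.

exemplar_cache <- new.env(parent = emptyenv())

cached_exemplar <- function() {
  if (is.null(exemplar_cache$kb)) {
    exemplar_cache$dir <- tempfile("exemplar_")
    exemplar_cache$bundle <- exemplar_bundle(exemplar_cache$dir)
    exemplar_cache$kb <- read_bundle(exemplar_cache$bundle)
    exemplar_cache$graph <- build_graph(exemplar_cache$kb)
    enr <- enrich_graph(exemplar_cache$graph, exemplar_cache$kb,
                        exemplar_cache$bundle$lexicon_path)
    exemplar_cache$enriched <- enr$graph
    exemplar_cache$mappings <- enr$mappings
  }
  exemplar_cache
}

# minimal hand-built KB pieces for violation tests
tiny_names <- function(text = "Testus exemplaris") name_record(text, "la")

tiny_code <- function(code, kind = "taxonomic", parent = NA, ...) {
  code_record(code, kind, tiny_names(paste("Testus", tolower(code))),
              created = "2001-01-01", parent = parent, code_type = "PLS",
              ...)
}

tiny_kb <- function(codes, ...) {
  assemble_kb(codes, types = exemplar_types_for_tests(), ...)
}

exemplar_scheme_small <- function() {
  categorization_scheme(
    data.frame(id = c("QuarantineOrganism", "QuarantinePest"),
               parent = c(NA, "QuarantineOrganism"), stringsAsFactors = FALSE),
    c("A1 list" = "QuarantinePest"))
}

exemplar_types_for_tests <- function() {
  code_types(c("PLS", "NTX"), c("Plant species", "Non Taxonomic"),
             c("plant", "non_taxonomic"))
}

drop_triples <- function(graph, s = NA, p = NA, o = NA) {
  df <- graph$triples
  drop <- rep(TRUE, nrow(df))
  if (!is.na(s)) drop <- drop & df$s == s
  if (!is.na(p)) drop <- drop & df$p == p
  if (!is.na(o)) drop <- drop & df$o == o
  g <- graph
  g$triples <- df[!drop, , drop = FALSE]
  rownames(g$triples) <- NULL
  g
}

eppo_iri <- function(code) paste0("https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/", code)
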