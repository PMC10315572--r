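#' @title SPARQL subset engine
#'
#' @description
#' Executes the SPARQL 1.1 fragment the competency-question harness needs:
#' `PREFIX` declarations, `SELECT [DISTINCT]` with a basic graph pattern and
#' flat `OPTIONAL` groups, and `ASK`. Joins are natural joins over shared
#' variables; `OPTIONAL` is a left join. Result rows are returned in a total
#' sort order so query evaluation is deterministic and independent of triple
#' insertion order.
#'
#' @name sparql
NULL

SPARQL_TOKEN_RE <- paste(
  c(
    "<[^<>\"{}|^`\\\\[:space:]]*>",
    "\"(?:[^\"\\\\]|\\\\.)*\"",
    "#[^\n]*",
    "@[A-Za-z][A-Za-z0-9-]*",
    "\\^\\^",
    "\\?[A-Za-z_][A-Za-z0-9_]*",
    "_:[A-Za-z0-9_][A-Za-z0-9_.-]*",
    "(?:[A-Za-z][A-Za-z0-9_-]*)?:(?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?",
    "[A-Za-z][A-Za-z0-9_]*",
    "[{};,.*]"
  ),
  collapse = "|"
)

sparql_tokenize <- function(query) {
  m <- gregexpr(SPARQL_TOKEN_RE, query, perl = TRUE)[[1L]]
  if (m[1L] == -1L) eppo_abort("empty SPARQL query", "eppo_query_error")
  toks <- regmatches(query, list(m))[[1L]]
  leftover <- query
  regmatches(leftover, list(m)) <- list(rep("", length(toks)))
  leftover <- gsub("[[:space:]]+", "", leftover)
  if (nzchar(leftover)) {
    eppo_abort(sprintf("SPARQL syntax error near '%s'", substr(leftover, 1L, 30L)),
               "eppo_query_error")
  }
  toks[!startsWith(toks, "#")]
}

# canonical term encodings shared by pattern matching and result binding
enc_subject <- function(s) ifelse(startsWith(s, "_:"), s, paste0("<", s, ">"))
enc_object <- function(o, o_kind, lang, dtype) {
  ifelse(o_kind == "iri", paste0("<", o, ">"),
         ifelse(o_kind == "bnode", o,
                paste0("\"", o, "\"",
                       ifelse(!is.na(lang), paste0("@", lang),
                              ifelse(!is.na(dtype), paste0("^^<", dtype, ">"), "")))))
}

#' Decode a canonical SPARQL binding
#'
#' IRIs come back as plain IRI strings, literals as their lexical form with
#' language tag and datatype stripped, blank nodes as their label.
#'
#' @param x character vector of canonical bindings.
#' @return character vector.
#' @export
sparql_decode <- function(x) {
  out <- x
  iri <- !is.na(x) & startsWith(x, "<")
  out[iri] <- substring(sub(">$", "", x[iri]), 2L)
  litm <- !is.na(x) & startsWith(x, "\"")
  out[litm] <- vapply(x[litm], function(v) {
    body <- sub("^\"((?:[^\"\\\\]|\\\\.)*)\".*$", "\\1", v)
    unescape_ttl_string(body)
  }, "")
  out
}

parse_sparql <- function(query) {
  toks <- sparql_tokenize(query)
  i <- 1L
  n <- length(toks)
  px <- character(0)
  peek <- function() if (i <= n) toks[i] else ""
  need <- function(what) {
    if (i > n) eppo_abort(sprintf("unexpected end of query, expected %s (position %d)",
                                  what, i), "eppo_query_error")
    t <- toks[i]; i <<- i + 1L; t
  }
  kw <- function(t) toupper(t)

  while (kw(peek()) == "PREFIX") {
    need("PREFIX")
    pfx <- sub(":$", "", need("prefix name"))
    iri <- need("namespace IRI")
    px[[pfx]] <- substr(iri, 2L, nchar(iri) - 1L)
  }

  expand <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    colon <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1L, colon - 1L)
    if (!pfx %in% names(px)) {
      eppo_abort(sprintf("undeclared prefix '%s' (token %d)", pfx, i - 1L),
                 "eppo_query_error")
    }
    paste0(px[[pfx]], substring(tok, colon + 1L))
  }

  parse_term <- function() {
    tok <- need("pattern term")
    if (startsWith(tok, "?")) return(list(kind = "var", value = substring(tok, 2L)))
    if (tok == "a") return(list(kind = "const", value = paste0("<", RDF_TYPE_IRI, ">")))
    if (startsWith(tok, "\"")) {
      val <- unescape_ttl_string(substr(tok, 2L, nchar(tok) - 1L))
      lang <- NA_character_; dtype <- NA_character_
      if (peek() == "^^") { i <<- i + 1L; dtype <- expand(need("datatype")) }
      else if (startsWith(peek(), "@")) lang <- tolower(substring(need("langtag"), 2L))
      return(list(kind = "const",
                  value = enc_object(val, "lit", lang, dtype)))
    }
    if (startsWith(tok, "_:")) return(list(kind = "const", value = tok))
    list(kind = "const", value = paste0("<", expand(tok), ">"))
  }

  parse_group <- function() {
    if (need("'{'") != "{") eppo_abort("expected '{'", "eppo_query_error")
    patterns <- list()
    optionals <- list()
    repeat {
      t <- peek()
      if (t == "}") { i <<- i + 1L; break }
      if (kw(t) == "OPTIONAL") {
        i <<- i + 1L
        optionals[[length(optionals) + 1L]] <- parse_group()
        next
      }
      s <- parse_term(); p <- parse_term(); o <- parse_term()
      patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
      if (peek() == ".") i <<- i + 1L
    }
    list(patterns = patterns, optionals = optionals)
  }

  form <- kw(need("SELECT or ASK"))
  if (form == "SELECT") {
    distinct <- FALSE
    if (kw(peek()) == "DISTINCT") { distinct <- TRUE; i <- i + 1L }
    vars <- character(0)
    while (startsWith(peek(), "?")) vars <- c(vars, substring(need("variable"), 2L))
    if (peek() == "*") { need("*"); vars <- NULL }
    if (kw(peek()) == "WHERE") i <- i + 1L
    group <- parse_group()
    list(form = "select", vars = vars, distinct = distinct, group = group)
  } else if (form == "ASK") {
    if (kw(peek()) == "WHERE") i <- i + 1L
    list(form = "ask", group = parse_group())
  } else {
    eppo_abort(sprintf("unsupported query form '%s' (position %d)", form, i - 1L),
               "eppo_query_error")
  }
}

match_pattern <- function(enc, pattern) {
  keep <- rep(TRUE, nrow(enc))
  for (slot in c("s", "p", "o")) {
    term <- pattern[[slot]]
    if (term$kind == "const") keep <- keep & enc[[slot]] == term$value
  }
  cand <- enc[keep, , drop = FALSE]
  out <- list()
  for (slot in c("s", "p", "o")) {
    term <- pattern[[slot]]
    if (term$kind == "var") {
      if (!is.null(out[[term$value]])) {
        # same variable twice in one pattern: enforce equality
        keep2 <- out[[term$value]] == cand[[slot]]
        cand <- cand[keep2, , drop = FALSE]
        for (v in names(out)) out[[v]] <- out[[v]][keep2]
      } else {
        out[[term$value]] <- cand[[slot]]
      }
    }
  }
  if (length(out) == 0L) {
    return(structure(data.frame(.matched = rep(TRUE, nrow(cand))), no_vars = TRUE))
  }
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
}

join_bindings <- function(a, b, left = FALSE) {
  if (is.null(a)) return(b)
  if (isTRUE(attr(b, "no_vars"))) {
    if (nrow(b) == 0L && !left) return(a[0L, , drop = FALSE])
    return(a)
  }
  common <- intersect(names(a), names(b))
  merged <- merge(a, b, by = common, all.x = left, sort = FALSE)
  merged
}

eval_group <- function(enc, group, seed = NULL) {
  bindings <- seed
  for (pat in group$patterns) {
    bindings <- join_bindings(bindings, match_pattern(enc, pat))
    if (!is.null(bindings) && nrow(bindings) == 0L) break
  }
  if (is.null(bindings)) {
    bindings <- structure(data.frame(.matched = TRUE), no_vars = TRUE)
  }
  for (opt in group$optionals) {
    opt_res <- eval_group(enc, opt)
    if (isTRUE(attr(opt_res, "no_vars"))) next
    bindings <- join_bindings(bindings, opt_res, left = TRUE)
  }
  bindings
}

#' Run a SPARQL query against a graph
#'
#' @param graph an [rdf_graph].
#' @param query SPARQL text (`SELECT` with optional `DISTINCT` and
#'   `OPTIONAL` groups, or `ASK`).
#' @return for `SELECT`: a data frame with one column per projected
#'   variable, rows sorted in a total order, values in canonical form
#'   (`<iri>`, `"literal"@lang`, `_:bnode`; see [sparql_decode()]). For
#'   `ASK`: a logical scalar.
#' @export
run_query <- function(graph, query) {
  q <- parse_sparql(query)
  df <- graph$triples
  enc <- if (nrow(df) == 0L) {
    data.frame(s = character(), p = character(), o = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      s = enc_subject(df$s),
      p = paste0("<", df$p, ">"),
      o = enc_object(df$o, df$o_kind, df$lang, df$dtype),
      stringsAsFactors = FALSE
    )
  }
  res <- eval_group(enc, q$group)
  matched <- nrow(res) > 0L
  if (q$form == "ask") return(matched)

  vars <- q$vars
  if (is.null(vars)) vars <- setdiff(names(res), ".matched")
  out <- data.frame(matrix(NA_character_, nrow = nrow(res), ncol = length(vars)),
                    stringsAsFactors = FALSE)
  names(out) <- vars
  for (v in vars) if (v %in% names(res)) out[[v]] <- as.character(res[[v]])
  if (q$distinct) out <- unique(out)
  if (nrow(out) > 0L) {
    keys <- lapply(out, function(col) ifelse(is.na(col), "", col))
    out <- out[do.call(stable_order, keys), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
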