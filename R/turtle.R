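#' @title Deterministic Turtle and RDF/XML serialization
#'
#' @description
#' Writes an [rdf_graph] to Turtle with a total sort order over triples
#' (subject, predicate, object, language, datatype; `rdf:type` first within a
#' subject) so that equal graphs always produce byte-identical files, and
#' reads the emitted subset of Turtle back into a graph. RDF/XML output is
#' available as a secondary exchange format.
#'
#' @name turtle
NULL

# ---- IRI shortening -------------------------------------------------------

# Turtle PN_LOCAL (restricted): may start with a digit (eppo:1TRZG is legal
# Turtle), must not end with '.'.
pn_local_ok <- function(x) {
  grepl("^[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", x) | x == ""
}

shorten_iri <- function(iri, prefixes) {
  ns <- unname(prefixes)
  for (i in order(-nchar(ns))) {
    if (startsWith(iri, ns[i])) {
      local <- substring(iri, nchar(ns[i]) + 1L)
      if (pn_local_ok(local) && !grepl("/", local, fixed = TRUE)) {
        return(paste0(names(prefixes)[i], ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

escape_ttl_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

render_object <- function(df, prefixes) {
  out <- character(nrow(df))
  is_iri <- df$o_kind == "iri"
  is_bn <- df$o_kind == "bnode"
  is_lit <- df$o_kind == "lit"
  if (any(is_iri)) out[is_iri] <- vapply(df$o[is_iri], shorten_iri, "", prefixes = prefixes)
  out[is_bn] <- df$o[is_bn]
  if (any(is_lit)) {
    body <- paste0("\"", escape_ttl_string(df$o[is_lit]), "\"")
    lang <- df$lang[is_lit]
    dtype <- df$dtype[is_lit]
    suffix <- ifelse(!is.na(lang), paste0("@", lang),
                     ifelse(!is.na(dtype),
                            paste0("^^", vapply(ifelse(is.na(dtype), "", dtype),
                                                shorten_iri, "", prefixes = prefixes)),
                            ""))
    out[is_lit] <- paste0(body, suffix)
  }
  out
}

RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

#' Serialize a graph to Turtle text
#'
#' @param graph an [rdf_graph].
#' @return a single Turtle string (UTF-8), deterministic for a given triple
#'   set and prefix map.
#' @export
write_turtle <- function(graph) {
  px <- graph$prefixes[stable_order(names(graph$prefixes))]
  header <- paste0("@prefix ", names(px), ": <", unname(px), "> .")
  df <- graph$triples
  if (nrow(df) == 0L) return(paste0(paste(header, collapse = "\n"), "\n"))

  # total order: IRI subjects before bnodes, rdf:type first inside a subject
  subj_kind <- ifelse(startsWith(df$s, "_:"), 1L, 0L)
  p_rank <- ifelse(df$p == RDF_TYPE_IRI, 0L, 1L)
  ord <- stable_order(
    sprintf("%d", subj_kind), df$s, sprintf("%d", p_rank), df$p,
    df$o_kind, df$o,
    ifelse(is.na(df$lang), "", df$lang), ifelse(is.na(df$dtype), "", df$dtype)
  )
  df <- df[ord, , drop = FALSE]

  subj_render <- ifelse(startsWith(df$s, "_:"), df$s,
                        vapply(df$s, shorten_iri, "", prefixes = px))
  pred_render <- ifelse(df$p == RDF_TYPE_IRI, "a",
                        vapply(df$p, shorten_iri, "", prefixes = px))
  obj_render <- render_object(df, px)

  blocks <- character(0)
  start <- which(!duplicated(df$s))
  stop_ <- c(start[-1L] - 1L, nrow(df))
  for (k in seq_along(start)) {
    i <- start[k]:stop_[k]
    lines <- paste0("    ", pred_render[i], " ", obj_render[i])
    body <- paste(lines, collapse = " ;\n")
    blocks[k] <- paste0(subj_render[start[k]], "\n", body, " .")
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

#' Serialize a graph to a file
#'
#' Triples are emitted in a total sort order so equal graphs yield
#' byte-identical files.
#'
#' @param graph an [rdf_graph].
#' @param path output file path.
#' @param format `"turtle"` (default) or `"rdfxml"`.
#' @return the path, invisibly.
#' @export
serialize_graph <- function(graph, path, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  text <- switch(format, turtle = write_turtle(graph), rdfxml = write_rdfxml(graph))
  write_text(text, path)
}

# ---- Turtle reader --------------------------------------------------------

TTL_TOKEN_RE <- paste(
  c(
    "<[^<>\"{}|^`\\\\[:space:]]*>",        # IRIREF
    "\"(?:[^\"\\\\]|\\\\.)*\"",            # STRING
    "#[^\n]*",                             # comment
    "@prefix|@base",                       # directives
    "@[A-Za-z][A-Za-z0-9-]*",              # LANGTAG
    "\\^\\^",
    "_:[A-Za-z0-9_][A-Za-z0-9_.-]*",       # blank node label
    # prefixed name: optional prefix, ':' and a restricted local part
    "(?:[A-Za-z][A-Za-z0-9_-]*)?:(?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?",
    "\\b(?:a|true|false)\\b",
    "[;,.]"
  ),
  collapse = "|"
)

unescape_ttl_string <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  out <- character(0)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      nxt <- chars[i + 1L]
      rep <- switch(nxt,
        "n" = "\n", "t" = "\t", "r" = "\r", "\"" = "\"", "\\" = "\\",
        "b" = "\b", "f" = "\f", "'" = "'", NULL
      )
      if (!is.null(rep)) {
        out <- c(out, rep); i <- i + 2L; next
      }
      if (nxt == "u" && i + 5L <= n) {
        code <- paste(chars[(i + 2L):(i + 5L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 6L; next
      }
      if (nxt == "U" && i + 9L <= n) {
        code <- paste(chars[(i + 2L):(i + 9L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 10L; next
      }
    }
    out <- c(out, ch)
    i <- i + 1L
  }
  paste(out, collapse = "")
}

ttl_tokenize <- function(text) {
  m <- gregexpr(TTL_TOKEN_RE, text, perl = TRUE)[[1L]]
  no_match <- m[1L] == -1L
  toks <- if (no_match) character(0) else regmatches(text, list(m))[[1L]]
  # coverage check: anything that is neither a token nor whitespace is a
  # syntax error
  leftover <- text
  if (!no_match) regmatches(leftover, list(m)) <- list(rep("", length(toks)))
  leftover <- gsub("[[:space:]]+", "", leftover)
  if (nzchar(leftover)) {
    eppo_abort(sprintf("Turtle syntax error near '%s'",
                       substr(leftover, 1L, 30L)), "eppo_parse_error")
  }
  toks[!startsWith(toks, "#")]
}

#' Parse Turtle text or a Turtle file into a graph
#'
#' Supports the subset emitted by [write_turtle()]: prefix directives, IRIs,
#' prefixed names, labelled blank nodes, language-tagged and typed literals,
#' `;`/`,` continuation and the `a` keyword.
#'
#' @param text Turtle source text (ignored when `path` is given).
#' @param path optional path to a `.ttl` file.
#' @param prefixes initial prefix map; directives in the document override it.
#' @return an [rdf_graph].
#' @export
read_turtle <- function(text = NULL, path = NULL, prefixes = default_prefixes()) {
  if (!is.null(path)) text <- read_text(path)
  toks <- ttl_tokenize(text)
  tb <- triple_builder()
  px <- prefixes
  i <- 1L
  n <- length(toks)

  expand <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    colon <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1L, colon - 1L)
    local <- substring(tok, colon + 1L)
    if (!pfx %in% names(px)) {
      eppo_abort(sprintf("undeclared prefix '%s'", pfx), "eppo_parse_error")
    }
    paste0(px[[pfx]], local)
  }
  peek <- function() if (i <= n) toks[i] else ""
  need <- function(what) {
    if (i > n) eppo_abort(sprintf("unexpected end of Turtle input, expected %s", what),
                          "eppo_parse_error")
    tok <- toks[i]; i <<- i + 1L; tok
  }

  XSD_BOOL <- "http://www.w3.org/2001/XMLSchema#boolean"

  parse_object <- function() {
    tok <- need("object")
    if (startsWith(tok, "\"")) {
      val <- unescape_ttl_string(substr(tok, 2L, nchar(tok) - 1L))
      lang <- NA_character_; dtype <- NA_character_
      if (peek() == "^^") {
        i <<- i + 1L
        dtype <- expand(need("datatype IRI"))
      } else if (startsWith(peek(), "@") && !peek() %in% c("@prefix", "@base")) {
        lang <- tolower(substring(need("langtag"), 2L))
      }
      return(list(o = val, kind = "lit", lang = lang, dtype = dtype))
    }
    if (tok %in% c("true", "false")) {
      return(list(o = tok, kind = "lit", lang = NA_character_, dtype = XSD_BOOL))
    }
    if (startsWith(tok, "_:")) {
      return(list(o = tok, kind = "bnode", lang = NA_character_, dtype = NA_character_))
    }
    list(o = expand(tok), kind = "iri", lang = NA_character_, dtype = NA_character_)
  }

  while (i <= n) {
    tok <- need("statement")
    if (tok == "@prefix") {
      pfx_tok <- need("prefix name")
      iri_tok <- need("namespace IRI")
      if (need("'.'") != ".") eppo_abort("malformed @prefix directive", "eppo_parse_error")
      pfx <- sub(":$", "", pfx_tok)
      px[[pfx]] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      next
    }
    if (tok == "@base") {
      need("base IRI"); need("'.'")
      next
    }
    subj <- if (startsWith(tok, "_:")) tok else expand(tok)
    repeat {
      vtok <- need("predicate")
      pred <- if (vtok == "a") RDF_TYPE_IRI else expand(vtok)
      repeat {
        obj <- parse_object()
        tb_add(tb, subj, pred, obj$o, obj$kind, obj$lang, obj$dtype)
        if (peek() == ",") { i <- i + 1L; next }
        break
      }
      sep <- need("';' or '.'")
      if (sep == ";") {
        if (peek() == ".") { i <- i + 1L; break }  # tolerate trailing ';'
        next
      }
      if (sep == ".") break
      eppo_abort(sprintf("unexpected token '%s'", sep), "eppo_parse_error")
    }
  }
  tb_graph(tb, px)
}

# ---- RDF/XML writer -------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

split_qname <- function(iri, prefixes) {
  ns <- unname(prefixes)
  for (k in order(-nchar(ns))) {
    if (startsWith(iri, ns[k])) {
      local <- substring(iri, nchar(ns[k]) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
        return(c(prefix = names(prefixes)[k], local = local))
      }
    }
  }
  eppo_abort(sprintf("no declared namespace covers predicate <%s>", iri),
             "eppo_io_error")
}

write_rdfxml <- function(graph) {
  px <- graph$prefixes[stable_order(names(graph$prefixes))]
  df <- graph$triples
  ord <- stable_order(df$s, df$p, df$o_kind, df$o,
                      ifelse(is.na(df$lang), "", df$lang),
                      ifelse(is.na(df$dtype), "", df$dtype))
  df <- df[ord, , drop = FALSE]
  decls <- paste0("  xmlns:", names(px), "=\"", xml_escape(unname(px)), "\"",
                  collapse = "\n")
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<rdf:RDF\n", decls, ">"))
  if (nrow(df) > 0L) {
    start <- which(!duplicated(df$s))
    stop_ <- c(start[-1L] - 1L, nrow(df))
    for (k in seq_along(start)) {
      s <- df$s[start[k]]
      open <- if (startsWith(s, "_:")) {
        paste0("  <rdf:Description rdf:nodeID=\"", substring(s, 3L), "\">")
      } else {
        paste0("  <rdf:Description rdf:about=\"", xml_escape(s), "\">")
      }
      out <- c(out, open)
      for (i in start[k]:stop_[k]) {
        qn <- split_qname(df$p[i], px)
        tag <- paste0(qn[["prefix"]], ":", qn[["local"]])
        out <- c(out, switch(df$o_kind[i],
          iri = paste0("    <", tag, " rdf:resource=\"", xml_escape(df$o[i]), "\"/>"),
          bnode = paste0("    <", tag, " rdf:nodeID=\"", substring(df$o[i], 3L), "\"/>"),
          lit = {
            attr <- if (!is.na(df$lang[i])) {
              paste0(" xml:lang=\"", df$lang[i], "\"")
            } else if (!is.na(df$dtype[i])) {
              paste0(" rdf:datatype=\"", xml_escape(df$dtype[i]), "\"")
            } else ""
            paste0("    <", tag, attr, ">", xml_escape(df$o[i]), "</", tag, ">")
          }))
      }
      out <- c(out, "  </rdf:Description>")
    }
  }
  paste0(paste(c(out, "</rdf:RDF>"), collapse = "\n"), "\n")
}
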