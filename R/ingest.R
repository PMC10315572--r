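#' @title Parsing the coding-system source bundle
#'
#' @description
#' Readers for the canonical source layout: a code table (SQLite database or
#' a directory of CSV files, one per table: `codes`, `names`, `links`), the
#' replaced-codes history (CSV), categorization lists (CSV), host-pest
#' relations (JSON arrays emulating REST payloads) and the expert
#' categorization-scheme config (YAML, which also carries taxonomy-level and
#' code-type definitions plus the ontology-header metadata). Parsing is
#' order-stable: re-parsing the same bundle yields identical record
#' sequences.
#'
#' @name source_ingest
NULL

CODES_COLUMNS <- c("code", "kind", "created", "modified", "active", "parent",
                   "code_type", "level_name", "level_distance", "comment")
NAMES_COLUMNS <- c("code", "text", "language", "role", "created", "modified",
                   "active", "authority")
LINKS_COLUMNS <- c("code", "link_kind", "target")

read_csv_table <- function(path, required) {
  if (!file.exists(path)) {
    eppo_abort(sprintf("source table not found: %s", path), "eppo_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    eppo_abort(sprintf("%s: missing required column(s) %s", basename(path),
                       paste(missing, collapse = ", ")), "eppo_schema_error")
  }
  df[, required, drop = FALSE]
}

#' Parse the code table
#'
#' @param path for the `csv` dialect, a directory containing `codes.csv`,
#'   `names.csv` and `links.csv`; for the `sqlite` dialect, a database file
#'   with tables `codes`, `names` and `links` of the same layout.
#' @param dialect `"csv"` or `"sqlite"`.
#' @return list of [code_record()] objects, ordered by code.
#' @export
parse_code_table <- function(path, dialect = c("csv", "sqlite")) {
  dialect <- match.arg(dialect)
  if (dialect == "sqlite") {
    tmp <- tempfile("sqlite_dump_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    sqlite_dump_csv(path, tmp, c("codes", "names", "links"))
    path <- tmp
  }
  codes_df <- read_csv_table(file.path(path, "codes.csv"), CODES_COLUMNS)
  names_df <- read_csv_table(file.path(path, "names.csv"), NAMES_COLUMNS)
  links_df <- read_csv_table(file.path(path, "links.csv"), LINKS_COLUMNS)

  bad_kind <- !is.na(links_df$link_kind) &
    !links_df$link_kind %in% c("part_of", "associated_with")
  if (any(bad_kind)) {
    eppo_abort(sprintf("links: unknown link_kind '%s'",
                       links_df$link_kind[bad_kind][1L]), "eppo_row_error")
  }

  name_rows <- split(names_df, names_df$code)
  link_rows <- split(links_df, links_df$code)

  records <- vector("list", nrow(codes_df))
  for (i in seq_len(nrow(codes_df))) {
    row <- codes_df[i, ]
    nm <- name_rows[[row$code]]
    if (is.null(nm) || nrow(nm) == 0L) {
      eppo_abort(sprintf("code %s has no rows in the names table", row$code),
                 "eppo_row_error")
    }
    names_frame <- do.call(rbind, lapply(seq_len(nrow(nm)), function(j) {
      name_record(nm$text[j], nm$language[j], nm$role[j], nm$created[j],
                  nm$modified[j], lgl1(nm$active[j], TRUE), nm$authority[j])
    }))
    lk <- link_rows[[row$code]]
    part_of <- if (is.null(lk)) character() else lk$target[lk$link_kind == "part_of"]
    assoc <- if (is.null(lk)) character() else lk$target[lk$link_kind == "associated_with"]
    records[[i]] <- code_record(
      code = row$code, kind = row$kind, names = names_frame,
      created = row$created, modified = row$modified,
      active = lgl1(row$active, TRUE), parent = row$parent,
      code_type = row$code_type, level_name = row$level_name,
      level_distance = row$level_distance,
      part_of = part_of, associated_with = assoc, comment = row$comment
    )
  }
  records[stable_order(vapply(records, function(r) r$code, ""))]
}

#' Parse the replaced-codes history
#'
#' @param path CSV file with columns `old_code`, `new_code`, `date` (blank
#'   date allowed).
#' @return data frame of [replacement_record()] rows.
#' @export
parse_replaced_codes <- function(path) {
  df <- read_csv_table(path, c("old_code", "new_code", "date"))
  if (nrow(df) == 0L) return(empty_replacements())
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    replacement_record(df$old_code[i], df$new_code[i], df$date[i])
  }))
}

#' Parse a phytosanitary categorization list
#'
#' @param path CSV file with columns `code`, `q_list`, `continent`,
#'   `country`, `iso_code`, `year_added`, `year_deleted`, `year_trans`.
#' @return data frame of [categorization_status()] rows.
#' @export
parse_categorization_list <- function(path) {
  df <- read_csv_table(path, c("code", "q_list", "continent", "country",
                               "iso_code", "year_added", "year_deleted",
                               "year_trans"))
  if (nrow(df) == 0L) return(empty_categorizations())
  as_year <- function(x, i) {
    if (is.na(x)) return(NA_integer_)
    if (!grepl("^[0-9]{1,4}$", x)) {
      eppo_abort(sprintf("%s row %d: non-numeric year '%s'", basename(path), i, x),
                 "eppo_row_error")
    }
    as.integer(x)
  }
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    categorization_status(
      df$code[i], df$q_list[i], df$continent[i], df$country[i], df$iso_code[i],
      as_year(df$year_added[i], i), as_year(df$year_deleted[i], i),
      as_year(df$year_trans[i], i)
    )
  }))
}

#' Parse host-pest relations
#'
#' @param path JSON file holding an array of objects with keys `pest`,
#'   `host` and `category`. Categories are slugified and registered on the
#'   fly; the registry of a KB is the set of categories seen.
#' @return data frame of [host_pest_relation()] rows, with the encountered
#'   category registry attached as attribute `categories`.
#' @export
parse_host_pest_relations <- function(path) {
  entries <- tryCatch(
    jsonlite::fromJSON(read_text(path), simplifyVector = FALSE),
    error = function(e) eppo_abort(sprintf("malformed JSON in %s: %s", path,
                                           conditionMessage(e)), "eppo_parse_error")
  )
  if (length(entries) == 0L) {
    out <- empty_relations()
    attr(out, "categories") <- character(0)
    return(out)
  }
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    for (k in c("pest", "host", "category")) {
      if (is.null(e[[k]])) {
        eppo_abort(sprintf("relation entry %d: missing key '%s'", i, k),
                   "eppo_row_error")
      }
    }
    host_pest_relation(e$pest, e$host, e$category)
  })
  out <- do.call(rbind, rows)
  attr(out, "categories") <- sort(unique(out$category))
  out
}

#' Parse the categorization-scheme config
#'
#' @param path YAML config with a `categorizations` sequence (maps with `id`
#'   and optional `parent`) and a `q_lists` mapping from database q-list
#'   nomenclature strings to categorization ids.
#' @return an [categorization_scheme()].
#' @export
parse_categorization_scheme <- function(path) {
  parse_scheme_config(path)$scheme
}

#' Parse the full scheme/config file
#'
#' Alongside the categorization scheme the config file carries the
#' expert-curated taxonomy-level definitions (`levels`), code-type
#' definitions (`types`) and the ontology-header metadata (`ontology`:
#' title, creator, license, versionInfo).
#'
#' @param path YAML config file.
#' @return list with elements `scheme`, `levels`, `types`, `ontology`.
#' @export
parse_scheme_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) eppo_abort(
                    sprintf("malformed YAML in %s: %s", path, conditionMessage(e)),
                    "eppo_parse_error"))
  cats <- cfg$categorizations %||% list()
  nodes <- data.frame(
    id = vapply(cats, function(x) chr1(x$id), ""),
    parent = vapply(cats, function(x) chr1(x$parent), ""),
    stringsAsFactors = FALSE
  )
  self_parent <- !is.na(nodes$parent) & nodes$parent == nodes$id
  if (any(self_parent)) {
    eppo_abort(sprintf("categorization '%s' is its own parent",
                       nodes$id[self_parent][1L]), "eppo_config_error")
  }
  qmap <- unlist(cfg$q_lists %||% list())
  scheme <- categorization_scheme(nodes, if (is.null(qmap)) character() else qmap)

  lv <- cfg$levels %||% list()
  levels <- taxonomy_levels(
    vapply(lv, function(x) chr1(x$id), ""),
    vapply(lv, function(x) chr1(x$xref), "")
  )
  ty <- cfg$types %||% list()
  types <- code_types(
    vapply(ty, function(x) chr1(x$id), ""),
    vapply(ty, function(x) chr1(x$label), ""),
    vapply(ty, function(x) chr1(x$group), "")
  )
  list(scheme = scheme, levels = levels, types = types,
       ontology = cfg$ontology %||% list())
}

#' Read and assemble a whole source bundle
#'
#' Convenience wrapper: parses every file of a bundle directory (or an
#' `eppo_source_bundle` object) and assembles the knowledge base.
#'
#' @param bundle an `eppo_source_bundle` or a directory produced by
#'   [exemplar_bundle()], [random_bundle()] or [write_bundle()].
#' @param dialect code-table dialect; defaults to the bundle's own.
#' @return an `eppo_kb`.
#' @export
read_bundle <- function(bundle, dialect = NULL) {
  if (is.character(bundle)) bundle <- locate_bundle(bundle)
  dialect <- dialect %||% bundle$dialect
  codes <- parse_code_table(bundle$code_table_path, dialect)
  replacements <- parse_replaced_codes(bundle$replaced_path)
  categorizations <- if (length(bundle$categorization_paths) == 0L) {
    empty_categorizations()
  } else {
    do.call(rbind, lapply(bundle$categorization_paths, parse_categorization_list))
  }
  relations <- parse_host_pest_relations(bundle$host_pest_path)
  cfg <- parse_scheme_config(bundle$scheme_path)
  assemble_kb(codes, relations, categorizations, replacements,
              cfg$scheme, cfg$levels, cfg$types)
}

locate_bundle <- function(dir) {
  if (!dir.exists(dir)) eppo_abort(sprintf("bundle directory not found: %s", dir),
                                   "eppo_io_error")
  sqlite <- file.path(dir, "codes.sqlite")
  dialect <- if (file.exists(sqlite)) "sqlite" else "csv"
  cat_files <- sort(list.files(dir, pattern = "^categorization.*\\.csv$",
                               full.names = TRUE))
  structure(list(
    dir = dir,
    code_table_path = if (dialect == "sqlite") sqlite else dir,
    replaced_path = file.path(dir, "replaced.csv"),
    categorization_paths = cat_files,
    host_pest_path = file.path(dir, "relations.json"),
    scheme_path = file.path(dir, "scheme.yaml"),
    lexicon_path = file.path(dir, "taxonomy.obo"),
    dialect = dialect
  ), class = "eppo_source_bundle")
}

# ---- SQLite bridge --------------------------------------------------------

# The sqlite dialect is handled through the system python interpreter's
# stdlib sqlite3 module (CSV in/out of a temp directory); the record-level
# parsing path is shared with the csv dialect.

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) eppo_abort("no python interpreter found for the sqlite dialect",
                             "eppo_io_error")
  p
}

run_python <- function(code, args) {
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script))
  writeLines(code, script)
  out <- suppressWarnings(system2(python_bin(), c(script, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    eppo_abort(sprintf("sqlite bridge failed: %s", paste(out, collapse = "; ")),
               "eppo_io_error")
  }
  invisible(out)
}

sqlite_dump_csv <- function(db, outdir, tables) {
  if (!file.exists(db)) eppo_abort(sprintf("database not found: %s", db), "eppo_io_error")
  run_python(c(
    "import sqlite3, csv, sys, os",
    "db, outdir = sys.argv[1], sys.argv[2]",
    "con = sqlite3.connect(db)",
    "for t in sys.argv[3:]:",
    "    cur = con.execute('SELECT * FROM \"%s\"' % t)",
    "    cols = [d[0] for d in cur.description]",
    "    with open(os.path.join(outdir, t + '.csv'), 'w', newline='', encoding='utf-8') as f:",
    "        w = csv.writer(f)",
    "        w.writerow(cols)",
    "        for row in cur:",
    "            w.writerow(['' if v is None else v for v in row])"
  ), c(db, outdir, tables))
}

sqlite_load_csv <- function(db, indir, tables) {
  run_python(c(
    "import sqlite3, csv, sys, os",
    "db, indir = sys.argv[1], sys.argv[2]",
    "if os.path.exists(db):",
    "    os.remove(db)",
    "con = sqlite3.connect(db)",
    "for t in sys.argv[3:]:",
    "    with open(os.path.join(indir, t + '.csv'), encoding='utf-8') as f:",
    "        r = csv.reader(f)",
    "        cols = next(r)",
    "        con.execute('CREATE TABLE \"%s\" (%s)' % (t, ', '.join('\"%s\" TEXT' % c for c in cols)))",
    "        rows = [[None if v == '' else v for v in row] for row in r]",
    "        if rows:",
    "            con.executemany('INSERT INTO \"%s\" VALUES (%s)' % (t, ', '.join('?' * len(cols))), rows)",
    "con.commit()"
  ), c(db, indir, tables))
}
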