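#' @title Domain model of an EPPO-style coding system
#'
#' @description
#' Record constructors and the knowledge-base assembly/validation layer.
#' A knowledge base (KB) aggregates code records (taxonomic, non-taxonomic
#' and commodity-group codes with their multilingual names), host-pest
#' relations, phytosanitary categorization statuses, the replaced-code
#' history, the expert categorization scheme, taxonomy-level definitions and
#' code-type definitions. Validation checks referential integrity (parents,
#' relation endpoints, categorization subjects, replacement targets) and the
#' forest shape of the parent hierarchy before anything is emitted as OWL.
#'
#' @name eppo_model
NULL

NAME_ROLES <- c("preferred", "alternative", "synonym")
CODE_KINDS <- c("taxonomic", "non_taxonomic", "commodity_group")

#' Create a name record
#'
#' One name attached to a code: the preferred (scientific) name, an
#' alternative name or a synonym, with its language tag and optional
#' provenance metadata (creation/modification dates, activity, naming
#' authority). Preferred scientific names conventionally carry the Latin
#' language tag `"la"`.
#'
#' @param text the name itself (non-empty).
#' @param language lowercase two-letter language tag.
#' @param role one of `"preferred"`, `"alternative"`, `"synonym"`.
#' @param created,modified optional ISO-8601 dates.
#' @param active logical activity flag.
#' @param authority optional naming authority (stored verbatim).
#' @return a one-row data frame.
#' @export
name_record <- function(text, language, role = "preferred",
                        created = NA, modified = NA, active = TRUE,
                        authority = NA) {
  text <- chr1(text)
  language <- tolower(chr1(language))
  if (is.na(text) || !nzchar(text)) eppo_abort("name text must be non-empty", "eppo_row_error")
  if (is.na(language) || !nzchar(language)) eppo_abort("name language must be non-empty", "eppo_row_error")
  if (!role %in% NAME_ROLES) {
    eppo_abort(sprintf("unknown name role '%s'", role), "eppo_row_error")
  }
  data.frame(
    text = text, language = language, role = role,
    created = check_date(chr1(created), "name created", text),
    modified = check_date(chr1(modified), "name modified", text),
    active = lgl1(active, TRUE),
    authority = chr1(authority),
    stringsAsFactors = FALSE
  )
}

empty_names <- function() {
  name_record("x", "la")[0L, , drop = FALSE]
}

canonical_names <- function(df) {
  role_rank <- match(df$role, NAME_ROLES)
  df <- df[stable_order(sprintf("%d", role_rank), df$language, df$text,
                        ifelse(is.na(df$created), "", df$created)), , drop = FALSE]
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Create a code record
#'
#' @param code 5-6 character uppercase alphanumeric identifier.
#' @param kind `"taxonomic"`, `"non_taxonomic"` or `"commodity_group"`.
#' @param names data frame of [name_record()] rows; exactly one `preferred`.
#' @param created creation date (ISO-8601, required).
#' @param modified optional modification date.
#' @param active logical activity flag.
#' @param parent optional parent code.
#' @param code_type id of a code-type definition.
#' @param level_name,level_distance taxonomy level id and the non-negative
#'   number of hierarchy steps separating the code from its kind root; only
#'   meaningful (and only allowed) on taxonomic codes.
#' @param part_of codes of the groups this (non-taxonomic or commodity)
#'   code is part of.
#' @param associated_with codes this code is associated with.
#' @param comment optional free-text definition/description of the code.
#' @return an object of class `eppo_code_record`.
#' @export
code_record <- function(code, kind, names, created, modified = NA,
                        active = TRUE, parent = NA, code_type = NA,
                        level_name = NA, level_distance = NA,
                        part_of = character(), associated_with = character(),
                        comment = NA) {
  code <- chr1(code)
  if (is.na(code) || !is_eppo_code(code)) {
    eppo_abort(sprintf("invalid EPPO code syntax: '%s'", code), "eppo_row_error")
  }
  if (!kind %in% CODE_KINDS) {
    eppo_abort(sprintf("%s: unknown code kind '%s'", code, kind), "eppo_row_error")
  }
  if (!is.data.frame(names) || nrow(names) == 0L) {
    eppo_abort(sprintf("%s: a code needs at least a preferred name", code), "eppo_row_error")
  }
  n_pref <- sum(names$role == "preferred")
  if (n_pref != 1L) {
    eppo_abort(sprintf("%s: expected exactly one preferred name, found %d", code, n_pref),
               "eppo_assembly_error")
  }
  created <- check_date(chr1(created), "code created", code)
  if (is.na(created)) eppo_abort(sprintf("%s: creation date required", code), "eppo_row_error")
  level_name <- chr1(level_name)
  level_distance <- int1(level_distance)
  if (kind != "taxonomic" && (!is.na(level_name) || !is.na(level_distance))) {
    eppo_abort(sprintf("%s: taxonomy level only allowed on taxonomic codes", code),
               "eppo_row_error")
  }
  if (!is.na(level_distance) && level_distance < 0L) {
    eppo_abort(sprintf("%s: taxonomy level distance must be non-negative", code),
               "eppo_row_error")
  }
  part_of <- sort(unique(as.character(part_of)))
  if (kind == "taxonomic" && length(part_of) > 0L) {
    eppo_abort(sprintf("%s: part_of only allowed on non-taxonomic/commodity codes", code),
               "eppo_row_error")
  }
  structure(
    list(
      code = code, kind = kind, names = canonical_names(names),
      created = created, modified = check_date(chr1(modified), "code modified", code),
      active = lgl1(active, TRUE), parent = chr1(parent),
      code_type = chr1(code_type),
      level_name = level_name, level_distance = level_distance,
      part_of = part_of,
      associated_with = sort(unique(as.character(associated_with))),
      comment = chr1(comment)
    ),
    class = "eppo_code_record"
  )
}

#' Create a host-pest relation
#'
#' @param pest,host distinct EPPO codes.
#' @param category relation category id (slugified, e.g. `"host"`,
#'   `"alternate"`, `"wild_weed"`).
#' @return one-row data frame.
#' @export
host_pest_relation <- function(pest, host, category) {
  pest <- chr1(pest); host <- chr1(host)
  if (is.na(pest) || is.na(host) || pest == host) {
    eppo_abort(sprintf("invalid host-pest relation %s/%s", pest, host), "eppo_row_error")
  }
  data.frame(pest = pest, host = host, category = slugify(chr1(category)),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(pest = character(), host = character(), category = character(),
             stringsAsFactors = FALSE)
}

#' Create a categorization status record
#'
#' One phytosanitary status of a taxonomic code in a region or country, keyed
#' by the database's categorization-list nomenclature (`q_list`).
#'
#' @param subject taxonomic EPPO code.
#' @param q_list categorization-list nomenclature string.
#' @param continent,country,iso_code optional location fields.
#' @param year_added,year_deleted,year_trans optional years.
#' @return one-row data frame.
#' @export
categorization_status <- function(subject, q_list, continent = NA, country = NA,
                                  iso_code = NA, year_added = NA,
                                  year_deleted = NA, year_trans = NA) {
  subject <- chr1(subject); q_list <- chr1(q_list)
  if (is.na(subject) || is.na(q_list)) {
    eppo_abort("categorization needs subject and q_list", "eppo_row_error")
  }
  ya <- int1(year_added); yd <- int1(year_deleted)
  if (!is.na(ya) && !is.na(yd) && yd < ya) {
    eppo_abort(sprintf("%s: year_deleted %d precedes year_added %d", subject, yd, ya),
               "eppo_row_error")
  }
  iso <- chr1(iso_code)
  if (!is.na(iso) && !grepl("^[A-Za-z]{2}$", iso)) {
    eppo_abort(sprintf("%s: invalid ISO-3166 code '%s'", subject, iso), "eppo_row_error")
  }
  data.frame(
    subject = subject, q_list = q_list, continent = chr1(continent),
    country = chr1(country), iso_code = if (is.na(iso)) NA_character_ else toupper(iso),
    year_added = ya, year_deleted = yd, year_trans = int1(year_trans),
    stringsAsFactors = FALSE
  )
}

empty_categorizations <- function() {
  categorization_status("XXXXX", "x")[0L, , drop = FALSE]
}

#' Create a replacement record
#'
#' @param old_code,new_code distinct codes; `old_code` was superseded by
#'   `new_code`.
#' @param date optional ISO-8601 date of the replacement.
#' @return one-row data frame.
#' @export
replacement_record <- function(old_code, new_code, date = NA) {
  old_code <- chr1(old_code); new_code <- chr1(new_code)
  if (is.na(old_code) || is.na(new_code) || old_code == new_code) {
    eppo_abort(sprintf("invalid replacement %s -> %s", old_code, new_code),
               "eppo_row_error")
  }
  data.frame(old_code = old_code, new_code = new_code,
             date = check_date(chr1(date), "replacement date", old_code),
             stringsAsFactors = FALSE)
}

empty_replacements <- function() {
  data.frame(old_code = character(), new_code = character(), date = character(),
             stringsAsFactors = FALSE)
}

#' Create a categorization scheme
#'
#' The expert-defined hierarchy of categorization classes (e.g.
#' `QuarantinePest` under `QuarantineOrganism`) plus the mapping from
#' database q-list nomenclature strings to those classes.
#'
#' @param nodes data frame with columns `id` and `parent` (`NA` for roots).
#' @param q_list_map named character vector: q-list string -> categorization id.
#' @return object of class `eppo_categorization_scheme`.
#' @export
categorization_scheme <- function(nodes = NULL, q_list_map = character()) {
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), parent = character(), stringsAsFactors = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent %||% rep(NA_character_, nrow(nodes)))
  if (anyDuplicated(nodes$id)) {
    eppo_abort("duplicate categorization id in scheme", "eppo_config_error")
  }
  bad_parent <- !is.na(nodes$parent) & !(nodes$parent %in% nodes$id)
  if (any(bad_parent)) {
    eppo_abort(sprintf("scheme parent '%s' is not a defined categorization",
                       nodes$parent[bad_parent][1L]), "eppo_config_error")
  }
  cyc <- find_cycle(stats::setNames(nodes$parent, nodes$id))
  if (!is.null(cyc)) {
    eppo_abort(sprintf("categorization scheme has a parent cycle: %s",
                       paste(cyc, collapse = " -> ")), "eppo_config_error")
  }
  q_list_map <- vapply(q_list_map, as.character, "")
  bad_map <- !(unname(q_list_map) %in% nodes$id)
  if (any(bad_map)) {
    eppo_abort(sprintf("q_list map target '%s' is not a defined categorization",
                       unname(q_list_map)[bad_map][1L]), "eppo_config_error")
  }
  nodes <- nodes[stable_order(nodes$id), c("id", "parent"), drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, q_list_map = q_list_map[stable_order(names(q_list_map))]),
            class = "eppo_categorization_scheme")
}

# Detect a cycle in a named parent map (child -> parent); returns the cycle
# members or NULL.
find_cycle <- function(parent_map) {
  state <- stats::setNames(integer(length(parent_map)), names(parent_map)) # 0 new 1 open 2 done
  for (start in names(parent_map)) {
    if (state[[start]] != 0L) next
    path <- character(0)
    node <- start
    while (!is.na(node) && node %in% names(parent_map)) {
      if (state[[node]] == 2L) break
      if (state[[node]] == 1L) {
        return(sort(path[which(path == node)[1L]:length(path)]))
      }
      state[[node]] <- 1L
      path <- c(path, node)
      node <- parent_map[[node]]
    }
    state[path] <- 2L
  }
  NULL
}

#' Create taxonomy-level definitions
#'
#' @param id level names (Kingdom, Family, Species, ...), unique.
#' @param external_xref optional cross-references to the corresponding terms
#'   of an external taxonomy ontology (stored verbatim).
#' @return data frame with columns `id`, `external_xref`.
#' @export
taxonomy_levels <- function(id = character(), external_xref = NA) {
  id <- as.character(id)
  if (anyDuplicated(id)) eppo_abort("duplicate taxonomy level id", "eppo_config_error")
  df <- data.frame(id = id, external_xref = rep_len(as.character(external_xref), length(id)),
                   stringsAsFactors = FALSE)
  df <- df[stable_order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

TYPE_GROUPS <- c("plant", "animal", "microorganism", "plant_group",
                 "animal_group", "microorganism_group", "non_taxonomic",
                 "commodity")

#' Create code-type definitions
#'
#' @param id short type codes (e.g. `"NTX"`), unique.
#' @param label human-readable labels.
#' @param group coarse group each type belongs to (plant / animal /
#'   microorganism at species level, their higher-group counterparts,
#'   non-taxonomic, commodity).
#' @return data frame with columns `id`, `label`, `group`.
#' @export
code_types <- function(id = character(), label = character(), group = character()) {
  id <- as.character(id)
  if (anyDuplicated(id)) eppo_abort("duplicate code type id", "eppo_config_error")
  group <- as.character(group)
  bad <- !group %in% TYPE_GROUPS
  if (any(bad)) {
    eppo_abort(sprintf("unknown code type group '%s'", group[bad][1L]), "eppo_config_error")
  }
  df <- data.frame(id = id, label = as.character(label), group = group,
                   stringsAsFactors = FALSE)
  df <- df[stable_order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- Knowledge base -------------------------------------------------------

#' Assemble a knowledge base
#'
#' Cross-links the parsed sources into one indexed, deterministic structure.
#' Inputs are not mutated; duplicate code identifiers and codes with a
#' missing or duplicated preferred name are rejected here, everything else is
#' reported by [validate_kb()].
#'
#' @param codes list of [code_record()] objects.
#' @param relations data frame of [host_pest_relation()] rows.
#' @param categorizations data frame of [categorization_status()] rows.
#' @param replacements data frame of [replacement_record()] rows.
#' @param scheme an [categorization_scheme()].
#' @param levels data frame from [taxonomy_levels()].
#' @param types data frame from [code_types()].
#' @return object of class `eppo_kb`.
#' @export
assemble_kb <- function(codes = list(), relations = NULL, categorizations = NULL,
                        replacements = NULL, scheme = NULL, levels = NULL,
                        types = NULL) {
  relations <- relations %||% empty_relations()
  categorizations <- categorizations %||% empty_categorizations()
  replacements <- replacements %||% empty_replacements()
  scheme <- scheme %||% categorization_scheme()
  levels <- levels %||% taxonomy_levels()
  types <- types %||% code_types()

  ids <- vapply(codes, function(r) r$code, "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    eppo_abort(sprintf("duplicate code identifier: %s",
                       paste(sort(unique(dup)), collapse = ", ")),
               "eppo_assembly_error")
  }
  for (r in codes) {
    if (sum(r$names$role == "preferred") != 1L) {
      eppo_abort(sprintf("%s: exactly one preferred name required", r$code),
                 "eppo_assembly_error")
    }
  }
  codes <- stats::setNames(codes, ids)
  codes <- codes[stable_order(ids)]

  canon <- function(df, ...) {
    keys <- lapply(list(...), function(col) {
      v <- df[[col]]
      if (is.numeric(v)) sprintf("%012d", ifelse(is.na(v), 0, v)) else ifelse(is.na(v), "", v)
    })
    df <- df[do.call(stable_order, keys), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  relations <- canon(relations, "pest", "host", "category")
  relations <- relations[!duplicated(relations), , drop = FALSE]
  rownames(relations) <- NULL
  categorizations <- canon(categorizations, "subject", "q_list", "iso_code",
                           "country", "year_added")
  replacements <- canon(replacements, "old_code", "new_code")

  structure(
    list(
      codes = codes, relations = relations, categorizations = categorizations,
      replacements = replacements, scheme = scheme, levels = levels,
      types = types,
      categories = sort(unique(relations$category))
    ),
    class = "eppo_kb"
  )
}

#' @export
print.eppo_kb <- function(x, ...) {
  cat(sprintf(
    "<eppo_kb: %d codes (%d taxonomic), %d relations, %d categorizations, %d replacements>\n",
    length(x$codes),
    sum(vapply(x$codes, function(r) r$kind == "taxonomic", TRUE)),
    nrow(x$relations), nrow(x$categorizations), nrow(x$replacements)))
  invisible(x)
}

kb_parent_map <- function(kb) {
  stats::setNames(vapply(kb$codes, function(r) r$parent, ""), names(kb$codes))
}

#' Validate a knowledge base
#'
#' Runs every referential-integrity and shape rule and returns the findings;
#' nothing is thrown. Rules: parents exist and form a forest, relation
#' endpoints and categorization subjects exist (subjects taxonomic),
#' replacement endpoints exist and form no cycle, q-list strings resolve
#' through the scheme (unresolvable ones are warnings, mirroring the human
#' classification step of maintenance), replaced codes used as parents or
#' relation endpoints are warnings (history is preserved, not purged).
#'
#' @param kb an `eppo_kb`.
#' @param strict escalate warnings to errors.
#' @param lenient downgrade a missing parent to a warning (the emitter then
#'   attaches the orphan under its kind root).
#' @return object of class `eppo_validation_report` with data frames
#'   `errors` and `warnings` (columns `rule`, `subject`, `message`).
#' @export
validate_kb <- function(kb, strict = FALSE, lenient = FALSE) {
  stopifnot(inherits(kb, "eppo_kb"))
  finding <- function(rule, subject, message) {
    data.frame(rule = rule, subject = subject, message = message,
               stringsAsFactors = FALSE)
  }
  errors <- list()
  warnings <- list()
  err <- function(...) errors[[length(errors) + 1L]] <<- finding(...)
  wrn <- function(...) warnings[[length(warnings) + 1L]] <<- finding(...)

  ids <- names(kb$codes)
  replaced <- unique(kb$replacements$old_code)

  # parents ----
  pmap <- kb_parent_map(kb)
  for (code in ids) {
    p <- pmap[[code]]
    if (is.na(p)) next
    if (!p %in% ids) {
      msg <- sprintf("parent '%s' of code %s does not exist", p, code)
      if (lenient) wrn("parent_missing", code, msg) else err("parent_missing", code, msg)
    } else if (p %in% replaced) {
      wrn("parent_replaced", code,
          sprintf("parent '%s' of code %s is a replaced code", p, code))
    }
  }
  cyc <- find_cycle(pmap)
  if (!is.null(cyc)) {
    err("parent_cycle", cyc[1L],
        sprintf("parent cycle among codes {%s}", paste(sort(cyc), collapse = ", ")))
  }

  # intra-code links ----
  for (code in ids) {
    r <- kb$codes[[code]]
    for (t in r$part_of) {
      if (!t %in% ids) err("part_of_missing", code,
                           sprintf("part_of target '%s' of %s does not exist", t, code))
    }
    for (t in r$associated_with) {
      if (!t %in% ids) {
        err("associated_missing", code,
            sprintf("associated_with target '%s' of %s does not exist", t, code))
      } else if (kb$codes[[t]]$kind == "taxonomic") {
        wrn("associated_taxonomic", code,
            sprintf("associated_with target '%s' of %s is a taxonomic code", t, code))
      }
    }
    if (!is.na(r$code_type) && nrow(kb$types) > 0L && !r$code_type %in% kb$types$id) {
      err("code_type_unknown", code,
          sprintf("code type '%s' of %s is not defined", r$code_type, code))
    }
    if (!is.na(r$level_name) && nrow(kb$levels) > 0L && !r$level_name %in% kb$levels$id) {
      err("level_unknown", code,
          sprintf("taxonomy level '%s' of %s is not defined", r$level_name, code))
    }
  }

  # relations ----
  if (nrow(kb$relations) > 0L) {
    for (i in seq_len(nrow(kb$relations))) {
      rel <- kb$relations[i, ]
      for (endpoint in c(rel$pest, rel$host)) {
        if (!endpoint %in% ids) {
          err("relation_missing", endpoint,
              sprintf("relation endpoint '%s' (%s/%s, %s) does not exist",
                      endpoint, rel$pest, rel$host, rel$category))
        } else if (endpoint %in% replaced) {
          wrn("relation_replaced", endpoint,
              sprintf("relation endpoint '%s' is a replaced code", endpoint))
        }
      }
    }
  }

  # categorizations ----
  mapped <- names(kb$scheme$q_list_map)
  if (nrow(kb$categorizations) > 0L) {
    for (i in seq_len(nrow(kb$categorizations))) {
      st <- kb$categorizations[i, ]
      if (!st$subject %in% ids) {
        err("categorization_missing", st$subject,
            sprintf("categorization subject '%s' does not exist", st$subject))
      } else if (kb$codes[[st$subject]]$kind != "taxonomic") {
        err("categorization_nontaxonomic", st$subject,
            sprintf("categorization subject '%s' is not taxonomic", st$subject))
      }
      if (!st$q_list %in% mapped) {
        wrn("q_list_unmapped", st$subject,
            sprintf("q_list '%s' has no categorization mapping in the scheme", st$q_list))
      }
    }
  }

  # replacements ----
  if (nrow(kb$replacements) > 0L) {
    for (i in seq_len(nrow(kb$replacements))) {
      rp <- kb$replacements[i, ]
      if (!rp$old_code %in% ids) {
        err("replacement_missing", rp$old_code,
            sprintf("replaced code '%s' does not exist", rp$old_code))
      }
      if (!rp$new_code %in% ids) {
        err("replacement_missing", rp$new_code,
            sprintf("replacement target '%s' does not exist", rp$new_code))
      }
    }
    rmap <- stats::setNames(kb$replacements$new_code, kb$replacements$old_code)
    rcyc <- find_cycle(rmap)
    if (!is.null(rcyc)) {
      err("replacement_cycle", rcyc[1L],
          sprintf("replacement cycle among codes {%s}", paste(sort(rcyc), collapse = ", ")))
    }
  }

  bind <- function(lst) {
    if (length(lst) == 0L) {
      return(data.frame(rule = character(), subject = character(),
                        message = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, lst)
  }
  errors <- bind(errors)
  warnings <- bind(warnings)
  if (strict && nrow(warnings) > 0L) {
    errors <- rbind(errors, warnings)
    warnings <- warnings[0L, , drop = FALSE]
  }
  rownames(errors) <- NULL
  rownames(warnings) <- NULL
  structure(list(errors = errors, warnings = warnings),
            class = "eppo_validation_report")
}

#' @export
print.eppo_validation_report <- function(x, ...) {
  cat(sprintf("<eppo_validation_report: %d errors, %d warnings>\n",
              nrow(x$errors), nrow(x$warnings)))
  for (i in seq_len(nrow(x$errors))) {
    cat(sprintf("  ERROR [%s] %s\n", x$errors$rule[i], x$errors$message[i]))
  }
  for (i in seq_len(nrow(x$warnings))) {
    cat(sprintf("  warning [%s] %s\n", x$warnings$rule[i], x$warnings$message[i]))
  }
  invisible(x)
}

#' Follow replacement links to the terminal code
#'
#' For an active code this is the identity; for a superseded code the chain
#' of replacements is followed transitively to the current code.
#'
#' @param kb an `eppo_kb`.
#' @param code a code present in the KB (active or replaced).
#' @return the terminal code string.
#' @export
resolve_replacement <- function(kb, code) {
  stopifnot(inherits(kb, "eppo_kb"))
  if (!code %in% names(kb$codes)) {
    eppo_abort(sprintf("unknown code '%s'", code), "eppo_lookup_error")
  }
  rmap <- stats::setNames(kb$replacements$new_code, kb$replacements$old_code)
  seen <- character(0)
  cur <- code
  while (cur %in% names(rmap)) {
    if (cur %in% seen) {
      cycle <- seen[which(seen == cur)[1L]:length(seen)]
      eppo_abort(sprintf("replacement cycle: %s", paste(c(cycle, cur), collapse = " -> ")),
                 "eppo_cycle_error")
    }
    seen <- c(seen, cur)
    cur <- rmap[[cur]]
  }
  cur
}

#' Ancestor chain of a code
#'
#' @param kb an `eppo_kb`.
#' @param code a code present in the KB.
#' @return character vector of ancestors ordered from the immediate parent to
#'   the root; empty for root codes.
#' @export
lineage <- function(kb, code) {
  stopifnot(inherits(kb, "eppo_kb"))
  if (!code %in% names(kb$codes)) {
    eppo_abort(sprintf("unknown code '%s'", code), "eppo_lookup_error")
  }
  out <- character(0)
  cur <- kb$codes[[code]]$parent
  while (!is.na(cur)) {
    if (cur %in% out || cur == code) {
      eppo_abort(sprintf("parent cycle reached from '%s'", code), "eppo_cycle_error")
    }
    out <- c(out, cur)
    if (!cur %in% names(kb$codes)) break
    cur <- kb$codes[[cur]]$parent
  }
  out
}
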