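#' @title Compiling a knowledge base into an OWL graph
#'
#' @description
#' The emitter turns a validated knowledge base into an OWL 2 ontology graph.
#' Codes are modelled as OWL classes connected by direct object-property
#' triples (OWL 2 punning), which keeps the competency-question SPARQL
#' queries single-triple-pattern. The T-Box carries the schema classes, the
#' expert categorization hierarchy, taxonomy levels, code types and the
#' property declarations (one `has_pest_type_*` / `has_host_type_*` inverse
#' pair per relation category). The A-Box emits one class per code with its
#' multilingual names (metadata-bearing names reified as `owl:Axiom`
#' annotation nodes), dates, activity flag, type/taxonomy links, part-of and
#' association links, host-pest triples in both directions, categorization
#' status classes, and the deprecation triple pattern (`isActive` false,
#' `owl:deprecated` true, `obo:IAO_0100001`) on superseded codes.
#'
#' @name owl_emit
NULL

default_ontology_config <- function() {
  list(
    title = "EPPO ontology",
    creator = "eppoforge",
    license = "https://creativecommons.org/licenses/by/4.0/",
    versionInfo = "0.1.0"
  )
}

lit <- function(o, lang = NA_character_, dtype = NA_character_) {
  list(o = o, lang = lang, dtype = dtype)
}

# Name metadata that triggers an owl:Axiom reification node: any explicit
# date/authority, or an inactive name (the activity flag must survive).
name_needs_axiom <- function(nr) {
  !is.na(nr$created) || !is.na(nr$modified) || !is.na(nr$authority) || !nr$active
}

name_property <- function(role, vocab) {
  switch(role,
    preferred = IRI$label,
    alternative = IRI$alt_label,
    synonym = IRI$exact_synonym,
    eppo_abort(sprintf("unknown name role '%s'", role), "eppo_row_error")
  )
}

emit_axiom_node <- function(tb, counter, subject, property, nr, vocab) {
  counter$n <- counter$n + 1L
  node <- paste0("_:ax", counter$n)
  tb_add(tb, node, IRI$type, IRI$owl_axiom)
  tb_add(tb, node, IRI$ann_source, subject)
  tb_add(tb, node, IRI$ann_property, property)
  tb_add(tb, node, IRI$ann_target, nr$text, "lit", lang = nr$language)
  if (!is.na(nr$created)) {
    tb_add(tb, node, IRI$dct_created, nr$created, "lit", dtype = IRI$xsd_date)
  }
  if (!is.na(nr$modified)) {
    tb_add(tb, node, IRI$dct_modified, nr$modified, "lit", dtype = IRI$xsd_date)
  }
  if (!is.na(nr$authority)) {
    tb_add(tb, node, vocab$annotation_properties[["has_authority"]], nr$authority, "lit")
  }
  tb_add(tb, node, vocab$annotation_properties[["isActive"]],
         tolower(as.character(nr$active)), "lit", dtype = IRI$xsd_boolean)
  node
}

#' Assert a name literal with optional axiom annotation
#'
#' Adds the name triple for a [name_record()] row and, when the record
#' carries provenance metadata (creation/modification date, authority, or an
#' inactive flag), an `owl:Axiom` reification node holding those annotations
#' together with the activity flag.
#'
#' @param graph an [rdf_graph].
#' @param subject IRI of an existing subject in the graph.
#' @param property annotation property IRI (label / altLabel / exactSynonym).
#' @param name_record one-row data frame from [name_record()].
#' @param vocab vocabulary, defaults to the standard one.
#' @return the updated graph.
#' @export
annotate_literal <- function(graph, subject, property, name_record,
                             vocab = eppo_vocabulary()) {
  if (!rdf_has(graph, s = subject)) {
    eppo_abort(sprintf("subject <%s> not present in graph", subject),
               "eppo_precondition_error")
  }
  tb <- triple_builder()
  counter <- new.env(parent = emptyenv())
  # continue the deterministic axiom-node numbering used by the emitter
  counter$n <- sum(graph$triples$p == IRI$type & graph$triples$o == IRI$owl_axiom)
  nr <- name_record[1L, ]
  tb_add(tb, subject, property, nr$text, "lit", lang = nr$language)
  if (name_needs_axiom(nr)) {
    emit_axiom_node(tb, counter, subject, property, nr, vocab)
  }
  add <- tb_graph(tb, graph$prefixes)
  rdf_from_triples(rbind(graph$triples, add$triples), graph$prefixes)
}

# Deterministic, collision-checked IRIs for categorization statuses.
status_iris <- function(kb, vocab) {
  df <- kb$categorizations
  if (nrow(df) == 0L) return(character(0))
  iri <- vapply(seq_len(nrow(df)), function(i) {
    mint_iri(vocab, "status", list(subject = df$subject[i], q_list = df$q_list[i],
                                   iso = df$iso_code[i]))
  }, "")
  clash <- iri %in% iri[duplicated(iri)]
  if (any(clash)) {
    iri[clash] <- vapply(which(clash), function(i) {
      mint_iri(vocab, "status", list(subject = df$subject[i], q_list = df$q_list[i],
                                     iso = df$iso_code[i], year = df$year_added[i]))
    }, "")
  }
  if (anyDuplicated(iri)) {
    eppo_abort(sprintf("categorization status IRI collision after slugging: %s",
                       iri[duplicated(iri)][1L]), "eppo_mint_error")
  }
  iri
}

#' Build the ontology graph from a knowledge base
#'
#' @param kb a validated `eppo_kb`; the KB is validated internally and any
#'   error aborts the build.
#' @param vocab optional [eppo_vocabulary()]; defaults to one spanning the
#'   KB's relation-category registry.
#' @param config ontology-header metadata: list with `title`, `creator`,
#'   `license`, `versionInfo` (defaults supplied for missing entries).
#' @param lenient downgrade missing parents to warnings; orphans are
#'   attached under their kind class.
#' @return an [rdf_graph].
#' @export
build_graph <- function(kb, vocab = NULL, config = NULL, lenient = FALSE) {
  stopifnot(inherits(kb, "eppo_kb"))
  report <- validate_kb(kb, strict = FALSE, lenient = lenient)
  if (nrow(report$errors) > 0L) {
    eppo_abort(paste0("knowledge base has validation errors: ",
                      paste(report$errors$message, collapse = "; ")),
               "eppo_precondition_error")
  }
  vocab <- vocab %||% eppo_vocabulary(categories = kb$categories)
  missing_cat <- setdiff(kb$categories, vocab$categories)
  if (length(missing_cat) > 0L) {
    eppo_abort(sprintf("vocabulary lacks relation categories: %s",
                       paste(missing_cat, collapse = ", ")),
               "eppo_precondition_error")
  }
  cfg <- utils::modifyList(default_ontology_config(), as.list(config %||% list()))

  tb <- triple_builder()
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  base <- vocab$base_iri
  ann <- vocab$annotation_properties
  cls <- vocab$classes

  # ---- ontology header ----
  ont <- sub("/+$", "", base)
  tb_add(tb, ont, IRI$type, IRI$owl_ontology)
  if (!is.null(cfg$title)) tb_add(tb, ont, IRI$dct_title, cfg$title, "lit")
  if (!is.null(cfg$creator)) tb_add(tb, ont, IRI$dc_creator, cfg$creator, "lit")
  if (!is.null(cfg$license)) tb_add(tb, ont, IRI$dct_license, cfg$license, "lit")
  if (!is.null(cfg$versionInfo)) tb_add(tb, ont, IRI$version_info, cfg$versionInfo, "lit")

  # ---- T-Box: schema classes ----
  tb_add(tb, unname(cls), IRI$type, IRI$owl_class)
  tb_add(tb, unname(cls), IRI$label, names(cls), "lit")
  for (k in c("TaxonomicCode", "NonTaxonomicCode", "CommodityGroup")) {
    tb_add(tb, cls[[k]], IRI$subclass, cls[["EPPOCode"]])
  }

  # categorization hierarchy (expert scheme)
  nodes <- kb$scheme$nodes
  for (i in seq_len(nrow(nodes))) {
    iri <- mint_iri(vocab, "schema", nodes$id[i])
    tb_add(tb, iri, IRI$type, IRI$owl_class)
    tb_add(tb, iri, IRI$label, nodes$id[i], "lit")
    parent <- if (is.na(nodes$parent[i])) cls[["Categorization"]] else {
      mint_iri(vocab, "schema", nodes$parent[i])
    }
    tb_add(tb, iri, IRI$subclass, parent)
  }

  # taxonomy levels, each cross-referenced to the external taxonomy
  for (i in seq_len(nrow(kb$levels))) {
    iri <- mint_iri(vocab, "schema", kb$levels$id[i])
    tb_add(tb, iri, IRI$type, IRI$owl_class)
    tb_add(tb, iri, IRI$label, kb$levels$id[i], "lit")
    tb_add(tb, iri, IRI$subclass, cls[["EPPOCodeTaxonomyLevel"]])
    if (!is.na(kb$levels$external_xref[i])) {
      tb_add(tb, iri, IRI$db_xref, kb$levels$external_xref[i], "lit")
    }
  }

  # code types
  for (i in seq_len(nrow(kb$types))) {
    iri <- mint_iri(vocab, "schema", kb$types$id[i])
    tb_add(tb, iri, IRI$type, IRI$owl_class)
    tb_add(tb, iri, IRI$subclass, cls[["EPPOCodeType"]])
    tb_add(tb, iri, IRI$dc_identifier, kb$types$id[i], "lit")
    tb_add(tb, iri, IRI$label, kb$types$label[i], "lit")
  }

  # ---- T-Box: properties ----
  core_obj <- vocab$object_properties[
    c("has_categorization", "has_status", "has_taxonomy", "has_eppo_type",
      "has_pest", "has_host", "partOf", "isAssociatedWith")]
  tb_add(tb, unname(core_obj), IRI$type, IRI$owl_objprop)
  tb_add(tb, core_obj[["has_pest"]], IRI$inverse_of, core_obj[["has_host"]])
  tb_add(tb, core_obj[["has_host"]], IRI$inverse_of, core_obj[["has_pest"]])
  for (cat in vocab$categories) {
    pest_p <- vocab$object_properties[[paste0("has_pest_type_", cat)]]
    host_p <- vocab$object_properties[[paste0("has_host_type_", cat)]]
    tb_add(tb, c(pest_p, host_p), IRI$type, IRI$owl_objprop)
    tb_add(tb, pest_p, IRI$subprop, core_obj[["has_pest"]])
    tb_add(tb, host_p, IRI$subprop, core_obj[["has_host"]])
    tb_add(tb, pest_p, IRI$inverse_of, host_p)
    tb_add(tb, host_p, IRI$inverse_of, pest_p)
  }
  tb_add(tb, unname(vocab$datatype_properties), IRI$type, IRI$owl_dtprop)
  tb_add(tb, unname(vocab$declared_annotation_properties), IRI$type, IRI$owl_annprop)

  # ---- A-Box: codes as classes ----
  replaced_by <- split(kb$replacements, kb$replacements$old_code)
  ids <- names(kb$codes)
  for (code in ids) {
    r <- kb$codes[[code]]
    s <- mint_iri(vocab, "code", code)
    tb_add(tb, s, IRI$type, IRI$owl_class)
    parent_iri <- if (!is.na(r$parent) && r$parent %in% ids) {
      mint_iri(vocab, "code", r$parent)
    } else {
      cls[[KIND_CLASS[[r$kind]]]]
    }
    tb_add(tb, s, IRI$subclass, parent_iri)
    tb_add(tb, s, IRI$dc_identifier, code, "lit")
    tb_add(tb, s, IRI$dct_created, r$created, "lit", dtype = IRI$xsd_date)
    if (!is.na(r$modified)) {
      tb_add(tb, s, IRI$dct_modified, r$modified, "lit", dtype = IRI$xsd_date)
    }
    is_replaced <- code %in% names(replaced_by)
    active <- if (is_replaced) FALSE else r$active
    tb_add(tb, s, ann[["isActive"]], tolower(as.character(active)), "lit",
           dtype = IRI$xsd_boolean)
    if (!is.na(r$comment)) tb_add(tb, s, IRI$comment, r$comment, "lit")
    if (!is.na(r$code_type)) {
      tb_add(tb, s, vocab$object_properties[["has_eppo_type"]],
             mint_iri(vocab, "schema", r$code_type))
    }
    if (r$kind == "taxonomic") {
      if (!is.na(r$level_name)) {
        tb_add(tb, s, vocab$object_properties[["has_taxonomy"]],
               mint_iri(vocab, "schema", r$level_name))
      }
      if (!is.na(r$level_distance)) {
        tb_add(tb, s, vocab$datatype_properties[["has_taxonomy_level"]],
               as.character(r$level_distance), "lit", dtype = IRI$xsd_integer)
      }
    }
    for (t in r$part_of) {
      tb_add(tb, s, vocab$object_properties[["partOf"]], mint_iri(vocab, "code", t))
    }
    for (t in r$associated_with) {
      tb_add(tb, s, vocab$object_properties[["isAssociatedWith"]],
             mint_iri(vocab, "code", t))
    }
    # names with axiom-annotated metadata
    for (j in seq_len(nrow(r$names))) {
      nr <- r$names[j, ]
      p <- name_property(nr$role, vocab)
      tb_add(tb, s, p, nr$text, "lit", lang = nr$language)
      if (name_needs_axiom(nr)) emit_axiom_node(tb, counter, s, p, nr, vocab)
    }
    # deprecation pattern on superseded codes
    if (is_replaced) {
      tb_add(tb, s, IRI$deprecated, "true", "lit", dtype = IRI$xsd_boolean)
      rep_rows <- replaced_by[[code]]
      for (j in seq_len(nrow(rep_rows))) {
        new_iri <- mint_iri(vocab, "code", rep_rows$new_code[j])
        tb_add(tb, s, IRI$term_replaced_by, new_iri)
        if (!is.na(rep_rows$date[j])) {
          counter$n <- counter$n + 1L
          node <- paste0("_:ax", counter$n)
          tb_add(tb, node, IRI$type, IRI$owl_axiom)
          tb_add(tb, node, IRI$ann_source, s)
          tb_add(tb, node, IRI$ann_property, IRI$term_replaced_by)
          tb_add(tb, node, IRI$ann_target, new_iri)
          tb_add(tb, node, IRI$dct_created, rep_rows$date[j], "lit",
                 dtype = IRI$xsd_date)
        }
      }
    }
  }

  # ---- host-pest relations, both directions ----
  for (i in seq_len(nrow(kb$relations))) {
    rel <- kb$relations[i, ]
    host_iri <- mint_iri(vocab, "code", rel$host)
    pest_iri <- mint_iri(vocab, "code", rel$pest)
    tb_add(tb, host_iri,
           vocab$object_properties[[paste0("has_pest_type_", rel$category)]],
           pest_iri)
    tb_add(tb, pest_iri,
           vocab$object_properties[[paste0("has_host_type_", rel$category)]],
           host_iri)
  }

  # ---- categorization statuses ----
  st_iri <- status_iris(kb, vocab)
  qmap <- kb$scheme$q_list_map
  for (i in seq_len(nrow(kb$categorizations))) {
    st <- kb$categorizations[i, ]
    s <- st_iri[i]
    tb_add(tb, s, IRI$type, IRI$owl_class)
    tb_add(tb, s, IRI$subclass, cls[["CategorizationStatus"]])
    if (st$q_list %in% names(qmap)) {
      tb_add(tb, s, vocab$object_properties[["has_status"]],
             mint_iri(vocab, "schema", qmap[[st$q_list]]))
    }
    tb_add(tb, s, ann[["has_categorization_q_list"]], st$q_list, "lit")
    if (!is.na(st$continent)) {
      tb_add(tb, s, ann[["has_categorization_continent"]], st$continent, "lit")
    }
    if (!is.na(st$country)) {
      tb_add(tb, s, ann[["has_categorization_country"]], st$country, "lit")
    }
    if (!is.na(st$iso_code)) {
      tb_add(tb, s, ann[["has_categorization_iso_code"]], st$iso_code, "lit")
    }
    for (col in c("year_added", "year_deleted", "year_trans")) {
      if (!is.na(st[[col]])) {
        tb_add(tb, s, ann[[paste0("has_categorization_", col)]],
               as.character(st[[col]]), "lit", dtype = IRI$xsd_integer)
      }
    }
    tb_add(tb, mint_iri(vocab, "code", st$subject),
           vocab$object_properties[["has_categorization"]], s)
  }

  tb_graph(tb, vocab$prefixes)
}

# ---- metrics --------------------------------------------------------------

#' Ontology metrics
#'
#' A census of the emitted graph in the spirit of an ontology editor's
#' metrics panel: declared classes and properties, logical axioms (subclass,
#' subproperty, inverse and object/datatype property assertions) and the
#' total axiom count (all triples).
#'
#' @param graph an [rdf_graph].
#' @return object of class `eppo_metrics`: named list of counts.
#' @export
ontology_metrics <- function(graph) {
  df <- graph$triples
  typed <- function(class_iri) unique(df$s[df$p == IRI$type & df$o == class_iri])
  classes <- typed(IRI$owl_class)
  obj <- typed(IRI$owl_objprop)
  annp <- typed(IRI$owl_annprop)
  dtp <- typed(IRI$owl_dtprop)
  assertion <- df$p %in% c(obj, dtp)
  logical_ax <- sum(df$p %in% c(IRI$subclass, IRI$subprop, IRI$inverse_of)) +
    sum(assertion)
  structure(list(
    classes = length(classes),
    object_properties = length(obj),
    annotation_properties = length(annp),
    datatype_properties = length(dtp),
    logical_axioms = logical_ax,
    axioms = nrow(df)
  ), class = "eppo_metrics")
}

#' @export
print.eppo_metrics <- function(x, ...) {
  cat("Ontology metrics\n")
  for (k in names(x)) cat(sprintf("  %-22s %d\n", k, x[[k]]))
  invisible(x)
}

# ---- graph walk-back ------------------------------------------------------

#' Reconstruct a knowledge base from an emitted graph
#'
#' Inverse of [build_graph()]: walks the graph and rebuilds every code
#' record (names with their reified metadata, dates, flags, hierarchy,
#' links), the host-pest relations, categorization statuses and
#' replacements. Scheme/level/type configuration is only partially present
#' in a graph (the q-list map and type groups are compile-time config), so a
#' `config` from [parse_scheme_config()] may be supplied to restore it
#' exactly; otherwise a best-effort reconstruction is used.
#'
#' @param graph an [rdf_graph] produced by [build_graph()].
#' @param config optional list from [parse_scheme_config()].
#' @param base_iri ontology namespace.
#' @return an `eppo_kb`.
#' @export
kb_from_graph <- function(graph, config = NULL, base_iri = EPPO_BASE_IRI) {
  df <- graph$triples
  local_name <- function(iri) substring(iri, nchar(base_iri) + 1L)
  schema_iri <- function(name) paste0(base_iri, name)
  kind_iris <- stats::setNames(vapply(unname(KIND_CLASS), schema_iri, ""),
                               names(KIND_CLASS))

  sub_map <- df[df$p == IRI$subclass, c("s", "o")]
  parent_of <- stats::setNames(sub_map$o, sub_map$s) # first parent is enough below

  # classify subjects by climbing the subclass chain
  climb_kind <- function(s) {
    seen <- character(0)
    cur <- s
    while (!is.na(cur) && !cur %in% seen) {
      hit <- names(kind_iris)[kind_iris == cur]
      if (length(hit) == 1L) return(hit)
      seen <- c(seen, cur)
      nxt <- sub_map$o[sub_map$s == cur]
      cur <- if (length(nxt) > 0L) nxt[1L] else NA_character_
    }
    NA_character_
  }

  ident <- df[df$p == IRI$dc_identifier & df$o_kind == "lit", c("s", "o")]
  code_subjects <- ident$s[startsWith(ident$s, base_iri) &
                             ident$s == paste0(base_iri, ident$o) &
                             is_eppo_code(ident$o)]
  code_subjects <- code_subjects[!is.na(vapply(code_subjects, climb_kind, ""))]
  code_set <- stats::setNames(local_name(code_subjects), code_subjects)

  # index axiom-annotation nodes by (source, property, target text, lang)
  ax_nodes <- df$s[df$p == IRI$type & df$o == IRI$owl_axiom]
  ax_index <- list()
  for (node in ax_nodes) {
    rows <- df[df$s == node, , drop = FALSE]
    src <- rows$o[rows$p == IRI$ann_source][1L]
    prop <- rows$o[rows$p == IRI$ann_property][1L]
    tgt_row <- rows[rows$p == IRI$ann_target, , drop = FALSE][1L, ]
    key <- paste(src, prop, tgt_row$o,
                 ifelse(is.na(tgt_row$lang), "", tgt_row$lang), sep = "\r")
    ax_index[[key]] <- rows
  }
  ax_get <- function(rows, p) {
    v <- rows$o[rows$p == p]
    if (length(v) == 0L) NA_character_ else v[1L]
  }

  one <- function(s, p, default = NA_character_) {
    v <- df$o[df$s == s & df$p == p]
    if (length(v) == 0L) default else v[1L]
  }

  codes <- list()
  replacements <- list()
  for (s in code_subjects) {
    code <- code_set[[s]]
    kind <- climb_kind(s)
    sub_targets <- sub_map$o[sub_map$s == s]
    parent_codes <- sub_targets[sub_targets %in% code_subjects]
    parent <- if (length(parent_codes) > 0L) code_set[[parent_codes[1L]]] else NA_character_

    nm_rows <- list()
    for (role in NAME_ROLES) {
      p <- name_property(role, NULL)
      hits <- df[df$s == s & df$p == p & df$o_kind == "lit", , drop = FALSE]
      for (j in seq_len(nrow(hits))) {
        key <- paste(s, p, hits$o[j],
                     ifelse(is.na(hits$lang[j]), "", hits$lang[j]), sep = "\r")
        ax <- ax_index[[key]]
        nm_rows[[length(nm_rows) + 1L]] <- name_record(
          text = hits$o[j], language = hits$lang[j], role = role,
          created = if (is.null(ax)) NA else ax_get(ax, IRI$dct_created),
          modified = if (is.null(ax)) NA else ax_get(ax, IRI$dct_modified),
          active = if (is.null(ax)) TRUE else {
            ax_get(ax, schema_iri("isActive")) == "true"
          },
          authority = if (is.null(ax)) NA else ax_get(ax, schema_iri("has_authority"))
        )
      }
    }

    rep_targets <- df$o[df$s == s & df$p == IRI$term_replaced_by]
    for (t in rep_targets) {
      key <- paste(s, IRI$term_replaced_by, t, "", sep = "\r")
      ax <- ax_index[[key]]
      replacements[[length(replacements) + 1L]] <- replacement_record(
        code, local_name(t),
        if (is.null(ax)) NA else ax_get(ax, IRI$dct_created)
      )
    }

    type_iri <- one(s, schema_iri("has_eppo_type"))
    level_iri <- one(s, schema_iri("has_taxonomy"))
    dist <- one(s, schema_iri("has_taxonomy_level"))
    part_targets <- df$o[df$s == s & df$p == IRI$part_of]
    assoc_targets <- df$o[df$s == s & df$p == IRI$associated_with]

    codes[[length(codes) + 1L]] <- code_record(
      code = code, kind = kind, names = do.call(rbind, nm_rows),
      created = one(s, IRI$dct_created), modified = one(s, IRI$dct_modified),
      active = one(s, schema_iri("isActive")) == "true",
      parent = parent, code_type = if (is.na(type_iri)) NA else local_name(type_iri),
      level_name = if (is.na(level_iri)) NA else local_name(level_iri),
      level_distance = if (is.na(dist)) NA else as.integer(dist),
      part_of = local_name(part_targets),
      associated_with = local_name(assoc_targets),
      comment = one(s, IRI$comment)
    )
  }

  # relations from has_pest_type_* assertions (host side)
  pest_prefix <- schema_iri("has_pest_type_")
  rel_rows <- df[startsWith(df$p, pest_prefix) & df$s %in% code_subjects &
                   df$o %in% code_subjects, , drop = FALSE]
  relations <- if (nrow(rel_rows) == 0L) empty_relations() else {
    do.call(rbind, lapply(seq_len(nrow(rel_rows)), function(i) {
      host_pest_relation(pest = code_set[[rel_rows$o[i]]],
                         host = code_set[[rel_rows$s[i]]],
                         category = substring(rel_rows$p[i], nchar(pest_prefix) + 1L))
    }))
  }

  # categorization statuses
  status_subjects <- sub_map$s[sub_map$o == schema_iri("CategorizationStatus")]
  cat_links <- df[df$p == schema_iri("has_categorization"), c("s", "o")]
  cats <- list()
  for (s in status_subjects) {
    owner <- cat_links$s[cat_links$o == s]
    owner_code <- if (length(owner) > 0L) code_set[[owner[1L]]] else NA_character_
    yr <- function(p) {
      v <- one(s, schema_iri(p))
      if (is.na(v)) NA_integer_ else as.integer(v)
    }
    cats[[length(cats) + 1L]] <- categorization_status(
      subject = owner_code,
      q_list = one(s, schema_iri("has_categorization_q_list")),
      continent = one(s, schema_iri("has_categorization_continent")),
      country = one(s, schema_iri("has_categorization_country")),
      iso_code = one(s, schema_iri("has_categorization_iso_code")),
      year_added = yr("has_categorization_year_added"),
      year_deleted = yr("has_categorization_year_deleted"),
      year_trans = yr("has_categorization_year_trans")
    )
  }

  if (!is.null(config)) {
    scheme <- config$scheme
    levels <- config$levels
    types <- config$types
  } else {
    cat_subjects <- character(0)
    cat_root <- schema_iri("Categorization")
    frontier <- cat_root
    while (length(frontier) > 0L) {
      kids <- sub_map$s[sub_map$o %in% frontier]
      kids <- setdiff(kids, c(cat_subjects, cat_root))
      cat_subjects <- c(cat_subjects, kids)
      frontier <- kids
    }
    nodes <- data.frame(
      id = local_name(cat_subjects),
      parent = vapply(cat_subjects, function(s) {
        p <- sub_map$o[sub_map$s == s][1L]
        if (p == cat_root) NA_character_ else local_name(p)
      }, ""),
      stringsAsFactors = FALSE
    )
    # q-list map: recoverable only for q_lists observed on statuses
    qmap <- character(0)
    for (s in status_subjects) {
      ql <- one(s, schema_iri("has_categorization_q_list"))
      tgt <- one(s, schema_iri("has_status"))
      if (!is.na(ql) && !is.na(tgt)) qmap[[ql]] <- local_name(tgt)
    }
    scheme <- categorization_scheme(nodes, qmap)
    lev_subjects <- sub_map$s[sub_map$o == schema_iri("EPPOCodeTaxonomyLevel")]
    levels <- taxonomy_levels(
      local_name(lev_subjects),
      vapply(lev_subjects, function(s) one(s, IRI$db_xref), "")
    )
    type_subjects <- sub_map$s[sub_map$o == schema_iri("EPPOCodeType")]
    types <- code_types(
      local_name(type_subjects),
      vapply(type_subjects, function(s) one(s, IRI$label), ""),
      rep("non_taxonomic", length(type_subjects)) # group is config-only
    )
  }

  cats_df <- if (length(cats) == 0L) empty_categorizations() else do.call(rbind, cats)
  reps_df <- if (length(replacements) == 0L) empty_replacements() else {
    do.call(rbind, replacements)
  }
  assemble_kb(codes, relations, cats_df, reps_df, scheme, levels, types)
}

#' Compare two knowledge bases component by component
#'
#' @param a,b `eppo_kb` objects.
#' @param records_only compare only record-level content (codes, relations,
#'   categorizations, replacements) and ignore the scheme/level/type config.
#' @return logical.
#' @export
kb_equal <- function(a, b, records_only = FALSE) {
  cmp <- c("codes", "relations", "categorizations", "replacements")
  if (!records_only) cmp <- c(cmp, "scheme", "levels", "types")
  for (k in cmp) {
    if (!isTRUE(all.equal(a[[k]], b[[k]], check.attributes = FALSE))) return(FALSE)
  }
  TRUE
}
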