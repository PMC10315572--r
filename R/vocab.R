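#' @title Ontology vocabulary and IRI minting
#'
#' @description
#' The vocabulary is the single census of every IRI the emitter may use:
#' schema classes (EPPOCode and its taxonomic / non-taxonomic / commodity
#' subdivisions, categorization machinery, taxonomy levels, code types),
#' object properties (including the per-category `has_pest_type_*` /
#' `has_host_type_*` subproperty pairs), the `has_taxonomy_level` datatype
#' property and the annotation properties (activity flag, name authority,
#' categorization detail fields, deprecation and term replacement).
#' Externally defined properties are soft-reused by IRI: `obo:BFO_0000050`
#' (part of), `sio:SIO_001403` (is associated with), `obo:IAO_0100001`
#' (term replaced by).
#'
#' @name vocabulary
NULL

RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL  <- "http://www.w3.org/2002/07/owl#"
XSD  <- "http://www.w3.org/2001/XMLSchema#"

IRI <- list(
  type = paste0(RDF, "type"),
  subclass = paste0(RDFS, "subClassOf"),
  subprop = paste0(RDFS, "subPropertyOf"),
  label = paste0(RDFS, "label"),
  comment = paste0(RDFS, "comment"),
  owl_class = paste0(OWL, "Class"),
  owl_objprop = paste0(OWL, "ObjectProperty"),
  owl_dtprop = paste0(OWL, "DatatypeProperty"),
  owl_annprop = paste0(OWL, "AnnotationProperty"),
  owl_ontology = paste0(OWL, "Ontology"),
  owl_axiom = paste0(OWL, "Axiom"),
  ann_source = paste0(OWL, "annotatedSource"),
  ann_property = paste0(OWL, "annotatedProperty"),
  ann_target = paste0(OWL, "annotatedTarget"),
  inverse_of = paste0(OWL, "inverseOf"),
  deprecated = paste0(OWL, "deprecated"),
  version_info = paste0(OWL, "versionInfo"),
  alt_label = "http://www.w3.org/2004/02/skos/core#altLabel",
  exact_synonym = "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym",
  db_xref = "http://www.geneontology.org/formats/oboInOwl#hasDbXref",
  dc_identifier = "http://purl.org/dc/elements/1.1/identifier",
  dc_creator = "http://purl.org/dc/elements/1.1/creator",
  dct_created = "http://purl.org/dc/terms/created",
  dct_modified = "http://purl.org/dc/terms/modified",
  dct_title = "http://purl.org/dc/terms/title",
  dct_license = "http://purl.org/dc/terms/license",
  part_of = "http://purl.obolibrary.org/obo/BFO_0000050",
  associated_with = "http://semanticscience.org/resource/SIO_001403",
  term_replaced_by = "http://purl.obolibrary.org/obo/IAO_0100001",
  xsd_date = paste0(XSD, "date"),
  xsd_boolean = paste0(XSD, "boolean"),
  xsd_integer = paste0(XSD, "integer")
)

EPPO_BASE_IRI <- "https://ontology.basf.net/ontology/BASF/Bioscience/EPPO/"

SCHEMA_CLASSES <- c(
  "EPPOCode", "TaxonomicCode", "NonTaxonomicCode", "CommodityGroup",
  "CategorizationStatus", "Categorization", "EPPOCodeTaxonomyLevel",
  "EPPOCodeType"
)

KIND_CLASS <- c(
  taxonomic = "TaxonomicCode",
  non_taxonomic = "NonTaxonomicCode",
  commodity_group = "CommodityGroup"
)

#' Build the emitter vocabulary
#'
#' @param base_iri namespace under which every minted class and schema term
#'   lives. Default is the published EPPO ontology namespace.
#' @param categories character vector of host/pest relation category ids
#'   (slugs); one `has_pest_type_<c>` / `has_host_type_<c>` inverse
#'   subproperty pair is declared per category.
#' @return an object of class `eppo_vocabulary`: prefix map, class IRIs and
#'   property IRIs, each census entry appearing exactly once.
#' @export
eppo_vocabulary <- function(base_iri = EPPO_BASE_IRI, categories = character()) {
  categories <- sort(unique(slugify(categories)))
  schema <- function(name) paste0(base_iri, name)
  classes <- stats::setNames(vapply(SCHEMA_CLASSES, schema, ""), SCHEMA_CLASSES)

  obj_core <- c(
    has_categorization = schema("has_categorization"),
    has_status = schema("has_status"),
    has_taxonomy = schema("has_taxonomy"),
    has_eppo_type = schema("has_eppo_type"),
    has_pest = schema("has_pest"),
    has_host = schema("has_host"),
    partOf = IRI$part_of,
    isAssociatedWith = IRI$associated_with
  )
  pest_props <- stats::setNames(
    schema(paste0("has_pest_type_", categories)),
    paste0("has_pest_type_", categories)
  )
  host_props <- stats::setNames(
    schema(paste0("has_host_type_", categories)),
    paste0("has_host_type_", categories)
  )

  ann <- c(
    label = IRI$label,
    altLabel = IRI$alt_label,
    exactSynonym = IRI$exact_synonym,
    dbXref = IRI$db_xref,
    identifier = IRI$dc_identifier,
    created = IRI$dct_created,
    modified = IRI$dct_modified,
    comment = IRI$comment,
    deprecated = IRI$deprecated,
    isActive = schema("isActive"),
    has_authority = schema("has_authority"),
    termReplacedBy = IRI$term_replaced_by,
    has_categorization_continent = schema("has_categorization_continent"),
    has_categorization_country = schema("has_categorization_country"),
    has_categorization_iso_code = schema("has_categorization_iso_code"),
    has_categorization_q_list = schema("has_categorization_q_list"),
    has_categorization_year_added = schema("has_categorization_year_added"),
    has_categorization_year_deleted = schema("has_categorization_year_deleted"),
    has_categorization_year_trans = schema("has_categorization_year_trans")
  )

  vocab <- list(
    base_iri = base_iri,
    categories = categories,
    classes = classes,
    object_properties = c(obj_core, pest_props, host_props),
    datatype_properties = c(has_taxonomy_level = schema("has_taxonomy_level")),
    annotation_properties = ann,
    # annotation properties declared in the emitted T-Box (built-in
    # rdfs:label/rdfs:comment/owl:deprecated are left undeclared, as editors do)
    declared_annotation_properties = ann[!names(ann) %in% c("label", "comment", "deprecated")],
    prefixes = c(default_prefixes(), eppo = base_iri)
  )
  stopifnot(!anyDuplicated(c(vocab$object_properties, vocab$datatype_properties,
                             vocab$annotation_properties)))
  structure(vocab, class = "eppo_vocabulary")
}

#' Mint a deterministic IRI
#'
#' Code IRIs are `base + code`; schema IRIs are `base + name`; categorization
#' status IRIs are `base + subject + "_CAT_" + slug(q_list) + "_" + iso`
#' (lower-cased ISO country code, `xx` when absent), with the year added
#' appended by the emitter when two statuses would otherwise collide.
#'
#' @param vocab an `eppo_vocabulary`.
#' @param kind one of `"code"`, `"status"`, `"schema"`.
#' @param key for `code`/`schema`, a single string; for `status`, a list or
#'   named vector with `subject`, `q_list`, optional `iso` and `year`.
#' @return IRI string.
#' @export
mint_iri <- function(vocab, kind = c("code", "status", "schema"), key) {
  kind <- match.arg(kind)
  if (kind %in% c("code", "schema")) {
    key <- as.character(key)
    if (length(key) != 1L || is.na(key) || !nzchar(key)) {
      eppo_abort("IRI key must be a non-empty string", "eppo_mint_error")
    }
    return(paste0(vocab$base_iri, key))
  }
  key <- as.list(key)
  subject <- chr1(key$subject)
  q_list <- chr1(key$q_list)
  if (is.na(subject) || is.na(q_list)) {
    eppo_abort("status IRI needs subject and q_list", "eppo_mint_error")
  }
  iso <- chr1(key$iso)
  iri <- paste0(vocab$base_iri, subject, "_CAT_", slugify(q_list), "_",
                if (is.na(iso)) "xx" else tolower(iso))
  year <- int1(key$year)
  if (!is.na(year)) iri <- paste0(iri, "_", year)
  iri
}

#' @export
print.eppo_vocabulary <- function(x, ...) {
  cat(sprintf("<eppo_vocabulary: base %s; %d classes, %d object / %d annotation / %d datatype properties>\n",
              x$base_iri, length(x$classes), length(x$object_properties),
              length(x$annotation_properties), length(x$datatype_properties)))
  invisible(x)
}
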