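#' @title Maintenance diffing of knowledge-base versions
#'
#' @description
#' The coding system is dynamic (thousands of new codes a year), so
#' releases are compared at the knowledge-base level — a semantic diff that
#' serialization order can never pollute. The change report is the hook for
#' the human maintenance step: newly appearing categorization q-lists that
#' the scheme cannot classify are flagged for expert classification.
#'
#' @name release_ops
NULL

code_fields_flat <- function(r) {
  list(
    kind = r$kind, created = r$created, modified = r$modified,
    active = r$active, parent = r$parent, code_type = r$code_type,
    level_name = r$level_name, level_distance = r$level_distance,
    part_of = paste(r$part_of, collapse = "|"),
    associated_with = paste(r$associated_with, collapse = "|"),
    comment = r$comment,
    names = paste(apply(r$names, 1L, paste, collapse = "\r"), collapse = "\n")
  )
}

#' Diff two knowledge bases
#'
#' @param old_kb,new_kb validated `eppo_kb` objects.
#' @return object of class `eppo_change_report` with components
#'   `added_codes`, `removed_codes`, `modified_codes` (named list of changed
#'   field names per shared code), `newly_deprecated` (codes replaced in the
#'   new KB but not the old), `new_q_lists` (q-lists of the new KB that its
#'   scheme cannot classify and that were not already unclassified in the
#'   old KB) and `new_relation_categories`.
#' @export
diff_kb <- function(old_kb, new_kb) {
  stopifnot(inherits(old_kb, "eppo_kb"), inherits(new_kb, "eppo_kb"))
  old_ids <- names(old_kb$codes)
  new_ids <- names(new_kb$codes)
  shared <- intersect(old_ids, new_ids)

  modified <- list()
  for (code in shared) {
    a <- code_fields_flat(old_kb$codes[[code]])
    b <- code_fields_flat(new_kb$codes[[code]])
    changed <- names(a)[!mapply(identical, a, b)]
    if (length(changed) > 0L) modified[[code]] <- changed
  }

  structure(list(
    added_codes = sort(setdiff(new_ids, old_ids)),
    removed_codes = sort(setdiff(old_ids, new_ids)),
    modified_codes = modified,
    newly_deprecated = sort(setdiff(unique(new_kb$replacements$old_code),
                                    unique(old_kb$replacements$old_code))),
    new_q_lists = sort(setdiff(flag_unclassified(new_kb),
                               flag_unclassified(old_kb))),
    new_relation_categories = sort(setdiff(new_kb$categories, old_kb$categories))
  ), class = "eppo_change_report")
}

#' @export
print.eppo_change_report <- function(x, ...) {
  cat(sprintf(
    "<eppo_change_report: +%d / -%d codes, %d modified, %d newly deprecated, %d new q-lists, %d new relation categories>\n",
    length(x$added_codes), length(x$removed_codes), length(x$modified_codes),
    length(x$newly_deprecated), length(x$new_q_lists),
    length(x$new_relation_categories)))
  invisible(x)
}

#' Is a change report empty?
#'
#' @param report an `eppo_change_report`.
#' @return logical; `TRUE` when the two KBs agree on every modelled field.
#' @export
change_report_empty <- function(report) {
  length(report$added_codes) == 0L && length(report$removed_codes) == 0L &&
    length(report$modified_codes) == 0L && length(report$newly_deprecated) == 0L &&
    length(report$new_q_lists) == 0L && length(report$new_relation_categories) == 0L
}

#' Flag q-lists needing expert classification
#'
#' @param kb an `eppo_kb`.
#' @return sorted, deduplicated character vector of categorization q-list
#'   strings with no mapping in the KB's scheme.
#' @export
flag_unclassified <- function(kb) {
  stopifnot(inherits(kb, "eppo_kb"))
  q <- unique(kb$categorizations$q_list)
  sort(setdiff(q, names(kb$scheme$q_list_map)))
}

#' Serialize a change report to JSON
#'
#' @param report an `eppo_change_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_change_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = FALSE, pretty = TRUE,
                       null = "list")
  invisible(path)
}
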