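#' @title Competency-question validation
#'
#' @description
#' A competency question (CQ) is a natural-language requirement the ontology
#' must answer, operationalized as a SPARQL query plus an expected answer
#' set (or boolean) and a comparison mode. The harness runs each CQ against
#' an emitted graph and diffs observed against expected answers: IRIs are
#' compared exactly, string answers after language-tag stripping. Four CQs
#' covering the worked example ship with the package (taxon association,
#' crop-group membership and listing, treatment-method parts); suites are
#' YAML files so further questions can be added without code changes.
#'
#' @name cq_validate
NULL

#' Construct a competency question
#'
#' @param id short identifier (e.g. `"CQ1"`).
#' @param question the natural-language question.
#' @param query SPARQL SELECT or ASK text.
#' @param expected for boolean compare a logical; otherwise a list of rows,
#'   each a named list mapping variable names to expected values (IRIs as
#'   full strings, literals as bare text).
#' @param compare `"set_equal"`, `"subset"` or `"boolean"`.
#' @return object of class `eppo_cq`.
#' @export
competency_question <- function(id, question, query,
                                expected, compare = c("set_equal", "subset", "boolean")) {
  compare <- match.arg(compare)
  if (compare == "boolean" && !is.logical(expected)) {
    eppo_abort(sprintf("%s: boolean compare requires a logical expected value", id),
               "eppo_config_error")
  }
  if (compare != "boolean" && !is.list(expected)) {
    eppo_abort(sprintf("%s: %s compare requires a list of expected rows", id, compare),
               "eppo_config_error")
  }
  structure(list(id = id, question = question, query = query,
                 expected = expected, compare = compare),
            class = "eppo_cq")
}

cq_row_keys <- function(rows, vars) {
  vapply(rows, function(row) {
    paste(vapply(vars, function(v) {
      val <- row[[v]]
      if (is.null(val) || (length(val) == 1L && is.na(val))) "" else as.character(val)
    }, ""), collapse = "\t")
  }, "")
}

#' Evaluate one competency question
#'
#' @param graph an [rdf_graph].
#' @param cq an `eppo_cq`.
#' @return list with `id`, `status` (`"pass"`/`"fail"`), `observed`,
#'   `expected` and `diff` (missing/unexpected row keys).
#' @export
evaluate_cq <- function(graph, cq) {
  stopifnot(inherits(cq, "eppo_cq"))
  observed <- run_query(graph, cq$query)
  if (cq$compare == "boolean") {
    pass <- identical(as.logical(observed), as.logical(cq$expected))
    return(list(id = cq$id, status = if (pass) "pass" else "fail",
                observed = observed, expected = cq$expected,
                diff = if (pass) list() else list(observed = observed)))
  }
  vars <- sort(unique(unlist(lapply(cq$expected, names))))
  if (length(vars) == 0L) vars <- names(observed)
  dec <- observed
  for (v in names(dec)) dec[[v]] <- sparql_decode(dec[[v]])
  obs_keys <- unique(vapply(seq_len(nrow(dec)), function(i) {
    paste(vapply(vars, function(v) {
      if (!v %in% names(dec) || is.na(dec[i, v])) "" else dec[i, v]
    }, ""), collapse = "\t")
  }, ""))
  exp_keys <- unique(cq_row_keys(cq$expected, vars))
  missing <- setdiff(exp_keys, obs_keys)
  unexpected <- setdiff(obs_keys, exp_keys)
  pass <- if (cq$compare == "set_equal") {
    length(missing) == 0L && length(unexpected) == 0L
  } else {
    length(missing) == 0L
  }
  list(id = cq$id, status = if (pass) "pass" else "fail",
       observed = obs_keys, expected = exp_keys,
       diff = list(missing = missing, unexpected = unexpected))
}

#' Load a CQ suite from YAML
#'
#' The file is a sequence of maps with keys `id`, `question`, `query`,
#' `compare` and `expected` (a boolean, or a sequence of variable->value
#' maps).
#'
#' @param path YAML suite file.
#' @return list of `eppo_cq` objects.
#' @export
load_cq_suite <- function(path) {
  spec <- tryCatch(yaml::read_yaml(path),
                   error = function(e) eppo_abort(
                     sprintf("malformed CQ suite %s: %s", path, conditionMessage(e)),
                     "eppo_parse_error"))
  lapply(spec, function(item) {
    competency_question(
      id = chr1(item$id), question = chr1(item$question),
      query = chr1(item$query),
      expected = if (identical(item$compare, "boolean")) {
        isTRUE(item$expected)
      } else {
        item$expected %||% list()
      },
      compare = chr1(item$compare) %||% "set_equal"
    )
  })
}

#' Run a CQ suite against a graph
#'
#' @param graph an [rdf_graph].
#' @param suite list of `eppo_cq` objects.
#' @return object of class `eppo_cq_report`: per-question results plus
#'   summary counts.
#' @export
run_cq_suite <- function(graph, suite) {
  results <- lapply(suite, function(cq) evaluate_cq(graph, cq))
  statuses <- vapply(results, function(r) r$status, "")
  structure(list(
    results = stats::setNames(results, vapply(results, function(r) r$id, "")),
    passed = sum(statuses == "pass"),
    failed = sum(statuses == "fail"),
    total = length(results)
  ), class = "eppo_cq_report")
}

#' Run the built-in competency questions
#'
#' Executes the four CQs shipped with the package against a graph built from
#' a KB containing the worked-example codes: which taxon is associated with
#' the winter-wheat crop code, which crop groups a species belongs to,
#' whether two species share a crop group, and which codes (with labels and
#' descriptions) are part of the treatment-methods group.
#'
#' @param graph an [rdf_graph].
#' @return an `eppo_cq_report`.
#' @export
run_builtin_suite <- function(graph) {
  run_cq_suite(graph, builtin_cq_suite())
}

#' @rdname run_builtin_suite
#' @export
builtin_cq_suite <- function() {
  path <- system.file("extdata", "cq", "builtin.yaml", package = "eppoforge",
                      mustWork = TRUE)
  load_cq_suite(path)
}

#' @export
print.eppo_cq_report <- function(x, ...) {
  cat(sprintf("<eppo_cq_report: %d/%d passed>\n", x$passed, x$total))
  for (r in x$results) {
    cat(sprintf("  %s %s\n", if (r$status == "pass") "PASS" else "FAIL", r$id))
    if (r$status != "pass" && length(r$diff) > 0L) {
      if (length(r$diff$missing %||% character(0)) > 0L) {
        cat(sprintf("    missing: %s\n", paste(r$diff$missing, collapse = " | ")))
      }
      if (length(r$diff$unexpected %||% character(0)) > 0L) {
        cat(sprintf("    unexpected: %s\n", paste(r$diff$unexpected, collapse = " | ")))
      }
    }
  }
  invisible(x)
}

#' Serialize a CQ report to JSON
#'
#' @param report an `eppo_cq_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cq_report <- function(report, path) {
  out <- list(
    passed = report$passed, failed = report$failed, total = report$total,
    results = lapply(report$results, function(r) {
      list(id = r$id, status = r$status, diff = r$diff)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
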