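# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Slugify a free-text identifier
#'
#' Lowercases, replaces every run of non-alphanumeric characters with a single
#' underscore and trims leading/trailing underscores. Used to derive legal
#' property-name suffixes from relation categories (e.g. `"Wild/Weed"` ->
#' `"wild_weed"`) and IRI components from categorization-list nomenclature.
#'
#' @param x character vector.
#' @return character vector of slugs.
#' @examples
#' slugify("Wild/Weed")
#' @export
slugify <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# Classed condition constructor: every package error carries a specific class
# under the umbrella "eppo_error" so callers/tests can discriminate.
eppo_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "eppo_error", "error")))
}

is_iso_date <- function(x) {
  ok <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  ok[ok] <- !is.na(suppressWarnings(as.Date(x[ok], format = "%Y-%m-%d")))
  ok
}

# Validate an optional ISO date field; NA passes through.
check_date <- function(x, what, where) {
  bad <- !is.na(x) & !is_iso_date(x)
  if (any(bad)) {
    eppo_abort(
      sprintf("malformed date '%s' in %s (%s)", x[bad][1L], what, where),
      "eppo_row_error"
    )
  }
  x
}

# EPPO code syntax: 5-6 uppercase alphanumerics (printed codes such as 1TRZG
# carry leading digits even though codes are described as letter combinations).
is_eppo_code <- function(x) grepl("^[0-9A-Z]{5,6}$", x)

chr1 <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L])) NA_character_ else as.character(x[1L])
}

int1 <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L])) NA_integer_ else as.integer(x[1L])
}

lgl1 <- function(x, default = NA) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L])) return(default)
  if (is.logical(x)) return(x[1L])
  tolower(as.character(x[1L])) %in% c("true", "t", "1", "yes")
}

# Stable (radix) ordering on one or more character keys; locale-independent so
# serialization is byte-identical across platforms.
stable_order <- function(...) do.call(order, c(list(...), list(method = "radix")))

# Read a UTF-8 text file as a single string.
read_text <- function(path) {
  if (!file.exists(path)) eppo_abort(sprintf("file not found: %s", path), "eppo_io_error")
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

write_text <- function(text, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) eppo_abort(sprintf("directory not found: %s", dir), "eppo_io_error")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(enc2utf8(text), con, eos = NULL, useBytes = TRUE)
  invisible(path)
}
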