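# ST classification codes: parsing, taxonomy validation, hierarchical similarity.

.stpath_env <- new.env(parent = emptyenv())

stop_stpath <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "stpath_error", "error", "condition")))
}

#' The ST classification taxonomy
#'
#' Returns the embedded taxonomy table mapping the first two digits of an ST
#' code to their interaction-character labels: six level-1 location categories
#' (extracellular reception, plasma membrane, membrane-to-cytoplasm,
#' intracellular, cytoplasm-to-nucleoplasm, nucleoplasm-to-nucleoplasm) and
#' their level-2 action types. Rows with `level2 == "*"` carry the level-1
#' label.
#'
#' @param file Optional path to an alternative taxonomy TSV with columns
#'   `level1`, `level2` (integer or `"*"`), `label`. The packaged table is
#'   used when `NULL`.
#' @return A data frame with columns `level1` (integer), `level2` (character,
#'   `"*"` or an integer literal) and `label` (character).
#' @export
#' @examples
#' tab <- st_taxonomy()
#' subset(tab, level1 == 4 & level2 == "5")$label  # "Ubiquitination"
st_taxonomy <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.stpath_env$taxonomy)) {
      return(.stpath_env$taxonomy)
    }
    file <- system.file("extdata", "st_taxonomy.tsv", package = "stpath",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(file, colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("level1", "level2", "label")
  if (!all(need %in% names(tab))) {
    stop_stpath(sprintf("taxonomy file must have columns %s",
                        paste(need, collapse = ", ")), "stpath_io_error")
  }
  tab$level1 <- as.integer(tab$level1)
  key <- paste(tab$level1, tab$level2)
  if (anyDuplicated(key)) {
    stop_stpath("duplicated (level1, level2) rows in taxonomy", "stpath_io_error")
  }
  if (cache) .stpath_env$taxonomy <- tab
  tab
}

# valid level-2 integers for a level-1 digit; empty if level1 unknown
.level2_values <- function(level1, taxonomy = st_taxonomy()) {
  v <- taxonomy$level2[taxonomy$level1 == level1 & taxonomy$level2 != "*"]
  sort(as.integer(v))
}

.level1_values <- function(taxonomy = st_taxonomy()) {
  sort(unique(taxonomy$level1))
}

new_st_code <- function(levels) {
  structure(as.integer(levels), class = "st_code")
}

#' Parse and validate an ST code
#'
#' An ST code is a four-level dot-separated code, e.g. `"4.5.1.1"`: the first
#' digit gives the cellular location of the interaction, the second the action
#' type (both validated against [st_taxonomy()]), the third characterizes the
#' entity pair, the fourth is a serial number. Levels 3 and 4 are opaque
#' positive integers with no enumerated vocabulary.
#'
#' @param text A single code string; surrounding whitespace is tolerated.
#' @param taxonomy Taxonomy table, see [st_taxonomy()].
#' @return An `st_code` object (an integer vector of the four levels).
#' @export
#' @examples
#' parse_st_code("4.5.1.1")
#' st_similarity("4.1.1.1", "4.1.1.2")
parse_st_code <- function(text, taxonomy = st_taxonomy()) {
  if (inherits(text, "st_code")) {
    return(text)
  }
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_stpath("ST code must be a single character string", "stpath_parse_error")
  }
  raw <- trimws(text)
  fields <- strsplit(raw, ".", fixed = TRUE)[[1]]
  if (length(fields) != 4L) {
    stop_stpath(sprintf("malformed ST code '%s': expected 4 dot-separated fields, got %d",
                        raw, length(fields)), "stpath_parse_error")
  }
  ok <- grepl("^[0-9]+$", fields)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop_stpath(sprintf("malformed ST code '%s': field %d ('%s') is not a non-negative integer",
                        raw, bad, fields[bad]), "stpath_parse_error")
  }
  lv <- as.integer(fields)
  l1s <- .level1_values(taxonomy)
  if (!(lv[1] %in% l1s)) {
    stop_stpath(sprintf("ST code '%s': level 1 is %d, taxonomy admits %s",
                        raw, lv[1], paste(range(l1s), collapse = "..")),
                "stpath_taxonomy_error")
  }
  l2s <- .level2_values(lv[1], taxonomy)
  if (!(lv[2] %in% l2s)) {
    stop_stpath(sprintf("ST code '%s': level 2 is %d, taxonomy admits %s under level 1 = %d",
                        raw, lv[2],
                        if (length(l2s) == 1) as.character(l2s)
                        else paste(range(l2s), collapse = ".."),
                        lv[1]),
                "stpath_taxonomy_error")
  }
  if (lv[3] < 1L || lv[4] < 1L) {
    stop_stpath(sprintf("ST code '%s': levels 3 and 4 must be >= 1", raw),
                "stpath_taxonomy_error")
  }
  new_st_code(lv)
}

#' @export
format.st_code <- function(x, ...) paste(unclass(x), collapse = ".")

#' @export
as.character.st_code <- function(x, ...) format(x)

#' @export
print.st_code <- function(x, ...) {
  cat("<st_code>", format(x), "\n")
  invisible(x)
}

#' Hierarchical similarity of two ST codes
#'
#' The similarity sigma of two codes is quantized by the length of their
#' common prefix over the four levels: 0 when the level-1 digits differ, then
#' 0.25 per additional matching level up to 1 for identical codes. It is the
#' substitution score used by [align_pathways()].
#'
#' @param a,b ST codes (`st_code` objects or code strings).
#' @return A number in `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
st_similarity <- function(a, b) {
  a <- parse_st_code(a)
  b <- parse_st_code(b)
  eq <- unclass(a) == unclass(b)
  k <- match(FALSE, eq, nomatch = 5L) - 1L
  0.25 * k
}

#' Category labels of an ST code
#'
#' Looks up the level-1 (cellular location) and level-2 (action type) labels of
#' a code in the taxonomy. The level-1 digit also drives the edge-coloring
#' category in exported networks.
#'
#' @inheritParams st_similarity
#' @param code An ST code or code string.
#' @param taxonomy Taxonomy table, see [st_taxonomy()].
#' @return A named character vector with elements `level1` and `level2`.
#' @export
#' @examples
#' category_labels("2.3.1.1")
category_labels <- function(code, taxonomy = st_taxonomy()) {
  code <- parse_st_code(code, taxonomy)
  l1 <- taxonomy$label[taxonomy$level1 == code[1] & taxonomy$level2 == "*"]
  l2 <- taxonomy$label[taxonomy$level1 == code[1] &
                         taxonomy$level2 == as.character(code[2])]
  c(level1 = l1, level2 = l2)
}

#' Parse an ST code pattern with wildcards
#'
#' Patterns such as `"1.2.*.*"` (the style the taxonomy table prints) are used
#' for catalog queries only; pathways always carry fully specified codes.
#'
#' @param text Pattern string: four dot-separated fields, each an integer or
#'   `*`.
#' @param taxonomy Taxonomy table.
#' @return An `st_pattern` object (integer vector with `NA` at wildcards).
#' @export
parse_st_pattern <- function(text, taxonomy = st_taxonomy()) {
  raw <- trimws(text)
  fields <- strsplit(raw, ".", fixed = TRUE)[[1]]
  if (length(fields) != 4L) {
    stop_stpath(sprintf("malformed ST pattern '%s': expected 4 fields", raw),
                "stpath_parse_error")
  }
  ok <- fields == "*" | grepl("^[0-9]+$", fields)
  if (!all(ok)) {
    stop_stpath(sprintf("malformed ST pattern '%s': field %d", raw, which(!ok)[1]),
                "stpath_parse_error")
  }
  lv <- suppressWarnings(as.integer(fields))
  if (!is.na(lv[1]) && !(lv[1] %in% .level1_values(taxonomy))) {
    stop_stpath(sprintf("ST pattern '%s': level 1 out of taxonomy", raw),
                "stpath_taxonomy_error")
  }
  if (!is.na(lv[1]) && !is.na(lv[2]) && !(lv[2] %in% .level2_values(lv[1], taxonomy))) {
    stop_stpath(sprintf("ST pattern '%s': level 2 out of taxonomy", raw),
                "stpath_taxonomy_error")
  }
  structure(lv, class = "st_pattern")
}

#' @export
format.st_pattern <- function(x, ...) {
  f <- ifelse(is.na(unclass(x)), "*", as.character(unclass(x)))
  paste(f, collapse = ".")
}

#' @export
print.st_pattern <- function(x, ...) {
  cat("<st_pattern>", format(x), "\n")
  invisible(x)
}

#' Match an ST code against a wildcard pattern
#'
#' @param pattern An `st_pattern` or pattern string.
#' @param code An `st_code` or code string.
#' @return `TRUE` if every non-wildcard field of `pattern` equals the
#'   corresponding field of `code`.
#' @export
st_matches <- function(pattern, code) {
  if (!inherits(pattern, "st_pattern")) pattern <- parse_st_pattern(pattern)
  code <- parse_st_code(code)
  p <- unclass(pattern)
  all(is.na(p) | p == unclass(code))
}
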