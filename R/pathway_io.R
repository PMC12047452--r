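# Pathways and interaction catalogs: constructors, the two text input
# dialects (comma-separated ST codes / entity names) and TSV serialization.

#' Construct a pathway
#'
#' A pathway is an ordered, nonempty sequence of interactions; each
#' interaction is a directed entity pair carrying one validated ST code.
#' Self-loops (e.g. autophosphorylation) are allowed.
#'
#' @param id Pathway identifier.
#' @param source,target Character vectors of entity names, one per step.
#' @param st_code Character vector of ST codes, one per step.
#' @param placeholder Logical: were the entity names synthesized (code-string
#'   input) rather than supplied?
#' @return An `st_pathway` object: a list with elements `id` and `steps`
#'   (a data frame with columns `source`, `target`, `st_code`).
#' @export
#' @examples
#' pw <- new_pathway("p1", c("A", "B"), c("B", "C"), c("1.2.1.1", "4.1.1.1"))
#' pathway_length(pw)
new_pathway <- function(id, source, target, st_code, placeholder = FALSE) {
  if (length(source) == 0L) {
    stop_stpath(sprintf("pathway '%s' has no steps", id), "stpath_domain_error")
  }
  if (length(source) != length(target) || length(source) != length(st_code)) {
    stop_stpath("source, target and st_code must have equal length",
                "stpath_domain_error")
  }
  if (any(!nzchar(source)) || any(!nzchar(target))) {
    stop_stpath(sprintf("pathway '%s': empty entity name", id),
                "stpath_domain_error")
  }
  codes <- vapply(st_code, function(s) format(parse_st_code(s)), character(1),
                  USE.NAMES = FALSE)
  structure(list(
    id = as.character(id),
    steps = data.frame(source = as.character(source),
                       target = as.character(target),
                       st_code = codes,
                       stringsAsFactors = FALSE)
  ), class = "st_pathway", placeholder = placeholder)
}

#' @export
print.st_pathway <- function(x, ...) {
  cat(sprintf("<st_pathway> %s (%d steps)\n", x$id, nrow(x$steps)))
  cat(" ", paste(x$steps$st_code, collapse = ","), "\n")
  invisible(x)
}

#' Number of steps in a pathway
#' @param pw An `st_pathway`.
#' @return Integer step count.
#' @export
pathway_length <- function(pw) nrow(pw$steps)

#' ST-code sequence of a pathway
#' @param pw An `st_pathway`.
#' @return Character vector of canonical code strings, in step order.
#' @export
pathway_codes <- function(pw) pw$steps$st_code

# 4 x L integer matrix of code levels, for vectorized sigma computation
.code_level_matrix <- function(codes) {
  vapply(strsplit(codes, ".", fixed = TRUE),
         function(f) as.integer(f), integer(4))
}

#' Check consecutive-step chaining of a pathway
#'
#' Pathways are usually chains (each step starts at the previous step's
#' target) but may branch; violations are reported, not rejected.
#'
#' @param pw An `st_pathway`.
#' @return Integer vector of step indices i where step i's target differs
#'   from step i+1's source (empty when fully chained).
#' @export
chaining_breaks <- function(pw) {
  n <- nrow(pw$steps)
  if (n < 2L) return(integer(0))
  which(pw$steps$target[-n] != pw$steps$source[-1])
}

#' Parse a comma-separated ST code string into a pathway
#'
#' One of the two pathway input dialects: a string of ST codes separated by
#' commas (whitespace tolerated). The steps receive synthetic endpoint names
#' `<id>_n0 -> <id>_n1 -> ...` so the pathway can still enter network
#' construction.
#'
#' @param text Code string, e.g. `"1.2.1.1, 4.1.1.1"`.
#' @param id Identifier for the resulting pathway.
#' @return An `st_pathway` with placeholder entities.
#' @export
parse_code_string <- function(text, id = "query") {
  fields <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (length(fields) == 0L || (length(fields) == 1L && !nzchar(fields))) {
    stop_stpath("empty ST code string", "stpath_parse_error")
  }
  empty <- which(!nzchar(fields))
  if (length(empty)) {
    stop_stpath(sprintf("empty ST code at position %d", empty[1]),
                "stpath_parse_error")
  }
  codes <- character(length(fields))
  for (i in seq_along(fields)) {
    codes[i] <- tryCatch(format(parse_st_code(fields[i])), error = function(e) {
      stop_stpath(sprintf("invalid ST code at position %d: %s",
                          i, conditionMessage(e)),
                  class(e)[1])
    })
  }
  n <- length(codes)
  new_pathway(id,
              source = paste0(id, "_n", seq_len(n) - 1L),
              target = paste0(id, "_n", seq_len(n)),
              st_code = codes, placeholder = TRUE)
}

#' Resolve a comma-separated entity string into a pathway
#'
#' The second input dialect: a string of entity names. Every consecutive name
#' pair must resolve to an interaction in the catalog (the "sub database of
#' interactions"); all unresolvable pairs are reported at once.
#'
#' @param text Entity string, e.g. `"EGFR, GRB2, SOS1"`; at least two names.
#' @param catalog An [interaction_catalog()].
#' @param id Identifier for the resulting pathway.
#' @return An `st_pathway` whose steps carry the catalog's ST codes.
#' @export
resolve_entity_string <- function(text, catalog, id = "query") {
  names_ <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  if (any(!nzchar(names_))) {
    stop_stpath(sprintf("empty entity name at position %d", which(!nzchar(names_))[1]),
                "stpath_parse_error")
  }
  if (length(names_) < 2L) {
    stop_stpath("entity string must contain at least two entities (one interaction)",
                "stpath_domain_error")
  }
  src <- names_[-length(names_)]
  tgt <- names_[-1]
  key <- paste0(src, "\x1f", tgt)
  idx <- match(key, paste0(catalog$source, "\x1f", catalog$target))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    stop_stpath(sprintf("interaction(s) not in catalog: %s",
                        paste(sprintf("(%s -> %s)", src[miss], tgt[miss]),
                              collapse = ", ")),
                "stpath_resolve_error")
  }
  new_pathway(id, src, tgt, catalog$st_code[idx])
}

#' Construct an interaction catalog
#'
#' A catalog maps ordered entity pairs to ST codes; at most one entry per
#' (source, target) pair. Codes must be fully specified (no wildcards).
#'
#' @param source,target Character vectors of entity names.
#' @param st_code Character vector of ST codes.
#' @param interaction_id Optional character vector of interaction identifiers.
#' @return An `interaction_catalog`: a data frame with columns `source`,
#'   `target`, `st_code`, `interaction_id`.
#' @export
interaction_catalog <- function(source, target, st_code,
                                interaction_id = NULL) {
  if (is.null(interaction_id)) interaction_id <- rep(NA_character_, length(source))
  key <- paste0(source, "\x1f", target)
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- match(key[dup[1]], key)
    stop_stpath(sprintf("duplicate catalog entry for (%s -> %s): rows %d and %d",
                        source[dup[1]], target[dup[1]], first, dup[1]),
                "stpath_domain_error")
  }
  codes <- vapply(st_code, function(s) format(parse_st_code(s)), character(1),
                  USE.NAMES = FALSE)
  structure(data.frame(source = as.character(source),
                       target = as.character(target),
                       st_code = codes,
                       interaction_id = as.character(interaction_id),
                       stringsAsFactors = FALSE),
            class = c("interaction_catalog", "data.frame"))
}

#' Look up one interaction in a catalog
#' @param catalog An `interaction_catalog`.
#' @param source,target Entity names.
#' @return A one-row data frame, or `NULL` when the pair is absent.
#' @export
catalog_lookup <- function(catalog, source, target) {
  i <- which(catalog$source == source & catalog$target == target)
  if (!length(i)) return(NULL)
  catalog[i, , drop = FALSE]
}

#' Query a catalog by ST code pattern
#' @param catalog An `interaction_catalog`.
#' @param pattern An `st_pattern` or pattern string such as `"1.2.*.*"`.
#' @return The catalog rows whose code matches the pattern.
#' @export
catalog_query <- function(catalog, pattern) {
  if (!inherits(pattern, "st_pattern")) pattern <- parse_st_pattern(pattern)
  keep <- vapply(catalog$st_code, function(s) st_matches(pattern, s), logical(1))
  catalog[keep, , drop = FALSE]
}

#' Read pathways from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `pathway_id`,
#' `step_index` (0-based, contiguous within each pathway), `source`, `target`,
#' `st_code`. Chaining breaks (a step not starting at the previous target)
#' produce a warning, not an error.
#'
#' @param file Path to the TSV file.
#' @return A named list of `st_pathway` objects, in order of first appearance.
#' @export
read_pathway_tsv <- function(file) {
  tab <- utils::read.delim(file, colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("pathway_id", "step_index", "source", "target", "st_code")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_stpath(sprintf("pathway TSV '%s' missing column(s): %s",
                        file, paste(missing_cols, collapse = ", ")),
                "stpath_io_error")
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  if (!all(grepl("^[0-9]+$", tab$step_index))) {
    bad <- which(!grepl("^[0-9]+$", tab$step_index))[1]
    stop_stpath(sprintf("pathway TSV '%s' row %d: step_index not an integer",
                        file, bad), "stpath_io_error")
  }
  tab$step_index <- as.integer(tab$step_index)
  for (i in seq_len(nrow(tab))) {
    tryCatch(parse_st_code(tab$st_code[i]), error = function(e) {
      stop_stpath(sprintf("pathway TSV '%s' row %d: %s",
                          file, i, conditionMessage(e)),
                  class(e)[1])
    })
  }
  ids <- unique(tab$pathway_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (pid in ids) {
    rows <- tab[tab$pathway_id == pid, , drop = FALSE]
    rows <- rows[order(rows$step_index), , drop = FALSE]
    if (!identical(rows$step_index, seq_len(nrow(rows)) - 1L)) {
      stop_stpath(sprintf("pathway TSV '%s': pathway '%s' has non-contiguous step_index",
                          file, pid), "stpath_io_error")
    }
    pw <- new_pathway(pid, rows$source, rows$target, rows$st_code)
    brk <- chaining_breaks(pw)
    if (length(brk)) {
      warning(sprintf("pathway '%s': step(s) %s do not chain (target != next source)",
                      pid, paste(brk, collapse = ", ")), call. = FALSE)
    }
    out[[pid]] <- pw
  }
  out
}

#' Write pathways to TSV
#'
#' Inverse of [read_pathway_tsv()]: `read(write(x))` reproduces `x` field for
#' field.
#'
#' @param pathways A single `st_pathway` or a list of them.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_pathway_tsv <- function(pathways, file) {
  if (inherits(pathways, "st_pathway")) pathways <- list(pathways)
  rows <- do.call(rbind, lapply(pathways, function(pw) {
    data.frame(pathway_id = pw$id,
               step_index = seq_len(nrow(pw$steps)) - 1L,
               pw$steps, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read an interaction catalog from TSV
#'
#' Columns: `source`, `target`, `st_code`, optional `interaction_id`.
#' Duplicate (source, target) pairs and wildcard codes are load errors.
#'
#' @param file Path to the TSV file.
#' @return An `interaction_catalog`.
#' @export
read_catalog_tsv <- function(file) {
  tab <- utils::read.delim(file, colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("source", "target", "st_code")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_stpath(sprintf("catalog TSV '%s' missing column(s): %s",
                        file, paste(missing_cols, collapse = ", ")),
                "stpath_io_error")
  }
  for (i in seq_len(nrow(tab))) {
    if (grepl("*", tab$st_code[i], fixed = TRUE)) {
      stop_stpath(sprintf("catalog TSV '%s' row %d: wildcard code '%s' not allowed in catalog",
                          file, i, tab$st_code[i]), "stpath_io_error")
    }
    tryCatch(parse_st_code(tab$st_code[i]), error = function(e) {
      stop_stpath(sprintf("catalog TSV '%s' row %d: %s",
                          file, i, conditionMessage(e)),
                  class(e)[1])
    })
  }
  interaction_catalog(tab$source, tab$target, tab$st_code,
                      if ("interaction_id" %in% names(tab)) tab$interaction_id)
}

#' Write an interaction catalog to TSV
#' @param catalog An `interaction_catalog`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_catalog_tsv <- function(catalog, file) {
  utils::write.table(as.data.frame(catalog), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "NA")
  invisible(file)
}
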