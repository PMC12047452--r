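# Pairwise pathway alignment: gap-free-penalty dynamic programming over
# ST-code sequences, normalized by the longer pathway length.

# sigma matrix between two code sequences: 0.25 * common-prefix length
.sigma_matrix <- function(codes1, codes2) {
  m1 <- .code_level_matrix(codes1)  # 4 x L1
  m2 <- .code_level_matrix(codes2)  # 4 x L2
  L1 <- ncol(m1)
  L2 <- ncol(m2)
  S <- matrix(0, L1, L2)
  prefix <- matrix(TRUE, L1, L2)
  for (k in 1:4) {
    prefix <- prefix & outer(m1[k, ], m2[k, ], "==")
    S <- S + 0.25 * prefix
  }
  S
}

#' Align two coded pathways
#'
#' Scores two pathways by the best monotone matching of their ST-code
#' sequences under the hierarchical similarity [st_similarity()], with a gap
#' penalty of zero: skipped steps cost nothing, only matched code pairs
#' contribute. Because the substitution scores are non-negative and gaps are
#' free, the local (Smith-Waterman style) optimum coincides with the global
#' dynamic-programming value
#' `H[i,j] = max(H[i-1,j-1] + sigma(a_i, b_j), H[i-1,j], H[i,j-1])`.
#' The normalized similarity is the raw score divided by the longer pathway's
#' length, so it lies in `[0, 1]` and equals 1 exactly when the two code
#' sequences are identical.
#'
#' @param pw1 Query pathway (`st_pathway`).
#' @param pw2 Subject pathway (`st_pathway`).
#' @return An `alignment_result`: list with `query_id`, `subject_id`,
#'   `raw_score`, `similarity`, `L1`, `L2` and `matches`, a data frame of
#'   matched positions (`query_index`, `subject_index`, `sigma`) with both
#'   index columns strictly increasing. Traceback ties prefer a scoring
#'   diagonal step, then a query gap, then a subject gap, so the reported
#'   matching is deterministic; the score itself is tie-free.
#' @export
#' @examples
#' a <- parse_code_string("1.2.1.1,4.1.1.1,6.2.1.1", "a")
#' b <- parse_code_string("1.2.1.2,4.2.1.1,6.2.1.1", "b")
#' align_pathways(a, b)$similarity
align_pathways <- function(pw1, pw2) {
  L1 <- pathway_length(pw1)
  L2 <- pathway_length(pw2)
  if (L1 == 0L || L2 == 0L) {
    stop_stpath("cannot align an empty pathway (normalization undefined)",
                "stpath_domain_error")
  }
  S <- .sigma_matrix(pathway_codes(pw1), pathway_codes(pw2))
  H <- matrix(0, L1 + 1L, L2 + 1L)
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + S[i, j], H[i, j + 1L], H[i + 1L, j])
    }
  }
  raw <- H[L1 + 1L, L2 + 1L]
  # traceback: prefer a sigma>0 diagonal, then dropping a query step,
  # then dropping a subject step, then a zero-sigma diagonal
  qi <- integer(0); sj <- integer(0); sg <- numeric(0)
  i <- L1; j <- L2
  while (i > 0L && j > 0L) {
    h <- H[i + 1L, j + 1L]
    if (S[i, j] > 0 && h == H[i, j] + S[i, j]) {
      qi <- c(i, qi); sj <- c(j, sj); sg <- c(S[i, j], sg)
      i <- i - 1L; j <- j - 1L
    } else if (h == H[i, j + 1L]) {
      i <- i - 1L
    } else if (h == H[i + 1L, j]) {
      j <- j - 1L
    } else {
      i <- i - 1L; j <- j - 1L
    }
  }
  structure(list(
    query_id = pw1$id,
    subject_id = pw2$id,
    raw_score = raw,
    similarity = raw / max(L1, L2),
    L1 = L1,
    L2 = L2,
    matches = data.frame(query_index = qi, subject_index = sj, sigma = sg)
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s: similarity %.4f (raw %.2f, L1=%d, L2=%d, %d matched pairs)\n",
              x$query_id, x$subject_id, x$similarity, x$raw_score,
              x$L1, x$L2, nrow(x$matches)))
  invisible(x)
}

#' Brute-force alignment score by matching enumeration
#'
#' Independent oracle for [align_pathways()]: explicitly enumerates every
#' monotone matching of the two code sequences (recursing on the choice of the
#' first matched pair) and returns the maximum sigma sum. Exponential; bounded
#' to short pathways.
#'
#' @param pw1,pw2 Pathways with at most `max_len` steps each.
#' @param max_len Enumeration bound (default 8).
#' @return The maximum raw score over all monotone matchings.
#' @export
brute_force_score <- function(pw1, pw2, max_len = 8L) {
  L1 <- pathway_length(pw1)
  L2 <- pathway_length(pw2)
  if (L1 > max_len || L2 > max_len) {
    stop_stpath(sprintf("brute_force_score: pathway length exceeds bound %d", max_len),
                "stpath_domain_error")
  }
  S <- .sigma_matrix(pathway_codes(pw1), pathway_codes(pw2))
  recurse <- function(i, j) {
    best <- 0
    if (i > L1 || j > L2) return(best)
    for (a in i:L1) {
      for (b in j:L2) {
        best <- max(best, S[a, b] + recurse(a + 1L, b + 1L))
      }
    }
    best
  }
  recurse(1L, 1L)
}

#' Rank a collection of pathways against a query
#'
#' Aligns the query against every pathway in the collection and sorts the
#' results by similarity from high to low; ties are broken by subject id
#' (ascending) so the ranking is deterministic. A collection containing a
#' copy of the query ranks it first with similarity 1.
#'
#' @param query Query pathway.
#' @param collection Nonempty list of subject pathways.
#' @return A list of `alignment_result` objects, sorted; see
#'   [alignment_table()] for a tabular view.
#' @export
rank_against_collection <- function(query, collection) {
  if (length(collection) == 0L) {
    stop_stpath("empty pathway collection", "stpath_domain_error")
  }
  results <- lapply(collection, function(pw) align_pathways(query, pw))
  sims <- vapply(results, `[[`, numeric(1), "similarity")
  ids <- vapply(results, `[[`, character(1), "subject_id")
  results[order(-sims, ids, method = "radix")]
}

#' Tabulate alignment results
#'
#' @param results A list of `alignment_result` objects (e.g. from
#'   [rank_against_collection()]).
#' @return A data frame with columns `query_id`, `subject_id`, `similarity`,
#'   `raw_score`, `L1`, `L2`, `matches` (semicolon-joined `i:j` pairs).
#' @export
alignment_table <- function(results) {
  if (inherits(results, "alignment_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(query_id = r$query_id,
               subject_id = r$subject_id,
               similarity = r$similarity,
               raw_score = r$raw_score,
               L1 = r$L1,
               L2 = r$L2,
               matches = paste(sprintf("%d:%d", r$matches$query_index,
                                       r$matches$subject_index),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Write alignment results to TSV
#' @param results A list of `alignment_result` objects.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_alignment_tsv <- function(results, file) {
  utils::write.table(alignment_table(results), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
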