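# Deterministic synthetic generators: interaction catalogs, random-walk
# pathways, and level-wise code perturbation with a closed-form expected
# similarity. Everything is a pure function of its config (seed included);
# the global RNG state is saved and restored around every draw.

#' Configuration for the synthetic generators
#'
#' @param seed Integer seed; the same config always yields identical output.
#' @param n_entities Number of entities in the catalog.
#' @param n_interactions Number of distinct ordered entity pairs; at most
#'   `n_entities * (n_entities - 1)`.
#' @param n_pathways Number of pathways to generate.
#' @param length_range Integer `c(min, max)` pathway lengths, `min >= 1`.
#' @param mutation_rates Numeric `c(p1, p2, p3, p4)` in `[0, 1]`: per-level
#'   probabilities that [perturb_pathway()] re-draws that level of a code.
#' @param level34_cap Upper bound of the uniform range used when sampling
#'   levels 3 and 4 (default 5, keeping the 0.75 similarity branch reachable
#'   at useful frequency).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_entities = 30L, n_interactions = 60L,
                         n_pathways = 10L, length_range = c(3L, 8L),
                         mutation_rates = c(0.1, 0.1, 0.1, 0.1),
                         level34_cap = 5L) {
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[1] > length_range[2]) {
    stop_stpath("length_range must be c(min, max) with 1 <= min <= max",
                "stpath_domain_error")
  }
  if (length(mutation_rates) != 4L || any(mutation_rates < 0) ||
      any(mutation_rates > 1)) {
    stop_stpath("mutation_rates must be four probabilities in [0, 1]",
                "stpath_domain_error")
  }
  if (n_interactions > n_entities * (n_entities - 1)) {
    stop_stpath("n_interactions exceeds the number of ordered entity pairs",
                "stpath_domain_error")
  }
  structure(list(seed = as.integer(seed),
                 n_entities = as.integer(n_entities),
                 n_interactions = as.integer(n_interactions),
                 n_pathways = as.integer(n_pathways),
                 length_range = as.integer(length_range),
                 mutation_rates = as.numeric(mutation_rates),
                 level34_cap = as.integer(level34_cap)),
            class = "synth_config")
}

# run expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# one uniformly drawn valid ST code (levels 3/4 uniform in 1..cap)
.random_code <- function(taxonomy, cap) {
  l1 <- sample(.level1_values(taxonomy), 1L)
  l2s <- .level2_values(l1, taxonomy)
  l2 <- if (length(l2s) == 1L) l2s else sample(l2s, 1L)
  sprintf("%d.%d.%d.%d", l1, l2, sample.int(cap, 1L), sample.int(cap, 1L))
}

#' Generate a random interaction catalog
#'
#' Draws `n_interactions` distinct ordered entity pairs among
#' `n_entities` named entities (`E001`, `E002`, ...) and assigns each a valid
#' ST code sampled uniformly over the taxonomy (level 1 uniform, then a valid
#' level 2, levels 3/4 uniform in `1..level34_cap`).
#'
#' @param config A [synth_config()].
#' @return An `interaction_catalog` with `config$n_interactions` rows.
#' @export
generate_catalog <- function(config) {
  .with_seed(config$seed, {
    n <- config$n_entities
    ents <- sprintf("E%03d", seq_len(n))
    # ordered pairs indexed 1..n*(n-1), excluding the diagonal
    pair_idx <- sample.int(n * (n - 1L), config$n_interactions)
    src_i <- (pair_idx - 1L) %/% (n - 1L) + 1L
    off <- (pair_idx - 1L) %% (n - 1L) + 1L
    tgt_i <- ifelse(off >= src_i, off + 1L, off)
    taxonomy <- st_taxonomy()
    codes <- vapply(seq_along(pair_idx),
                    function(i) .random_code(taxonomy, config$level34_cap),
                    character(1))
    interaction_catalog(ents[src_i], ents[tgt_i], codes,
                        sprintf("I%04d", seq_along(pair_idx)))
  })
}

#' Generate pathways as random walks over a catalog
#'
#' Each pathway is a random walk over the catalog's source-to-target
#' relation: the next step is drawn among catalog entries whose source equals
#' the current target. When the walk dead-ends before reaching the drawn
#' length, it restarts from a fresh random catalog entry (so the requested
#' number and lengths of pathways are always met; such pathways are not
#' simple chains).
#'
#' @param catalog A nonempty `interaction_catalog`.
#' @param config A [synth_config()]; uses `seed`, `n_pathways`,
#'   `length_range`.
#' @return A named list of `st_pathway` objects (`PW001`, `PW002`, ...).
#' @export
generate_pathways <- function(catalog, config) {
  if (nrow(catalog) == 0L) {
    stop_stpath("catalog is empty", "stpath_domain_error")
  }
  .with_seed(config$seed + 1L, {
    span <- config$length_range[2] - config$length_range[1] + 1L
    lens <- config$length_range[1] - 1L +
      sample.int(span, config$n_pathways, replace = TRUE)
    lapply(stats::setNames(seq_len(config$n_pathways),
                           sprintf("PW%03d", seq_len(config$n_pathways))),
           function(k) {
      L <- lens[k]
      rows <- integer(L)
      cur <- sample.int(nrow(catalog), 1L)
      rows[1] <- cur
      for (i in seq_len(L - 1L)) {
        nxt <- which(catalog$source == catalog$target[cur])
        cur <- if (length(nxt)) nxt[sample.int(length(nxt), 1L)]
               else sample.int(nrow(catalog), 1L)  # dead end: restart
        rows[i + 1L] <- cur
      }
      new_pathway(sprintf("PW%03d", k), catalog$source[rows],
                  catalog$target[rows], catalog$st_code[rows])
    })
  })
}

#' Perturb a pathway's ST codes level by level
#'
#' Each code is mutated independently: level k is re-drawn with probability
#' `mutation_rates[k]`, where a re-draw samples uniformly from the valid
#' values for that level *excluding the current one* (a forced change; when
#' the valid range is a singleton — e.g. level 2 under level 1 = 5 — the
#' re-draw is a no-op). When a level changes, the levels below it are
#' re-sampled uniformly from their valid ranges so the code stays within the
#' taxonomy. Entity names are kept.
#'
#' With all rates 0 the pathway is returned unchanged; see
#' [expected_similarity()] for the closed-form expected per-position
#' similarity this mutation model induces.
#'
#' @param pw An `st_pathway`.
#' @param config A [synth_config()]; uses `seed`, `mutation_rates`,
#'   `level34_cap`.
#' @return A new `st_pathway` with id `<id>_mut`.
#' @export
perturb_pathway <- function(pw, config) {
  taxonomy <- st_taxonomy()
  p <- config$mutation_rates
  cap <- config$level34_cap
  .with_seed(config$seed + 2L, {
    codes <- vapply(pathway_codes(pw), function(code) {
      lv <- as.integer(strsplit(code, ".", fixed = TRUE)[[1]])
      cascade <- FALSE
      for (k in 1:4) {
        domain <- switch(k,
                         .level1_values(taxonomy),
                         .level2_values(lv[1], taxonomy),
                         seq_len(cap),
                         seq_len(cap))
        if (cascade && !(lv[k] %in% domain)) {
          lv[k] <- domain[sample.int(length(domain), 1L)]
          cascade <- TRUE
          next
        }
        if (stats::runif(1) < p[k]) {
          alt <- setdiff(domain, lv[k])
          if (length(alt)) {
            lv[k] <- alt[sample.int(length(alt), 1L)]
            cascade <- TRUE
          }
        }
      }
      sprintf("%d.%d.%d.%d", lv[1], lv[2], lv[3], lv[4])
    }, character(1), USE.NAMES = FALSE)
    new_pathway(paste0(pw$id, "_mut"), pw$steps$source, pw$steps$target,
                codes, placeholder = isTRUE(attr(pw, "placeholder")))
  })
}

#' Closed-form expected similarity under the perturbation model
#'
#' For each position, the expected code similarity against the original is
#' `E[sigma] = 0.25 q1 (1 + q2 (1 + q3 (1 + q4)))` where `q_k` is the
#' probability that level k survives given all higher levels survived:
#' `1 - p_k` when the level's valid range offers an alternative value, 1 when
#' the range is a singleton (a forced change is impossible). The function
#' returns the mean over positions — the expected positional (diagonal)
#' similarity of the pathway against its perturbed copy. The alignment
#' similarity of the pair is bounded below by this quantity (re-alignment can
#' only help) and coincides with it except when several level-1 mutations
#' conspire to create a better off-diagonal matching.
#'
#' @param pw The original `st_pathway`.
#' @param config A [synth_config()] carrying `mutation_rates`.
#' @return Expected mean per-position similarity in `[0, 1]`.
#' @export
expected_similarity <- function(pw, config) {
  taxonomy <- st_taxonomy()
  p <- config$mutation_rates
  cap <- config$level34_cap
  per_pos <- vapply(pathway_codes(pw), function(code) {
    lv <- as.integer(strsplit(code, ".", fixed = TRUE)[[1]])
    sizes <- c(length(.level1_values(taxonomy)),
               length(.level2_values(lv[1], taxonomy)),
               max(cap, lv[3]), max(cap, lv[4]))
    # level survives iff not re-drawn, or no alternative exists
    q <- ifelse(sizes > 1L, 1 - p, 1)
    # a current value above the cap is always lost on re-draw: q unchanged
    0.25 * q[1] * (1 + q[2] * (1 + q[3] * (1 + q[4])))
  }, numeric(1), USE.NAMES = FALSE)
  mean(per_pos)
}
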