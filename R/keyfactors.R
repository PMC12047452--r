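# Key-node identification: weighted-PageRank transition matrix and the
# damped power iteration over the merged pathway network.

#' Configuration for node ranking
#'
#' Defaults follow the published analysis settings: damping factor
#' `d = 0.85`, iteration accuracy `epsilon = 1e-8`.
#'
#' Two transition-matrix normalizations are provided. `"in_weights"` divides
#' the weight of each incoming edge of node i by the total in-weight of i (the
#' printed form of the transition matrix); `"out_weights"` is the standard
#' weighted-PageRank variant dividing by the total out-weight of the source
#' node, which makes the matrix column-stochastic and conserves the rank sum.
#'
#' @param damping Damping factor d in (0, 1).
#' @param tolerance Convergence threshold epsilon on the change of the rank
#'   vector between iterations.
#' @param max_iterations Iteration cap; hitting it flags non-convergence.
#' @param normalization `"in_weights"` (default) or `"out_weights"`.
#' @param norm Norm for the convergence test: `"L1"` (default) or `"Linf"`.
#' @return A `rank_config` list.
#' @export
rank_config <- function(damping = 0.85, tolerance = 1e-8,
                        max_iterations = 10000L,
                        normalization = c("in_weights", "out_weights"),
                        norm = c("L1", "Linf")) {
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop_stpath("damping must be in (0, 1)", "stpath_domain_error")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop_stpath("tolerance must be positive", "stpath_domain_error")
  }
  if (max_iterations < 1L) {
    stop_stpath("max_iterations must be a positive integer", "stpath_domain_error")
  }
  structure(list(damping = damping, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 normalization = match.arg(normalization),
                 norm = match.arg(norm)),
            class = "rank_config")
}

# node-pair weight matrix W with W[i, j] = total weight of edges j -> i
# (parallel ST-coded edges between the same pair are summed)
.pair_weight_matrix <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- net$edges
  ti <- match(e$target, nodes)
  si <- match(e$source, nodes)
  for (k in seq_len(nrow(e))) {
    W[ti[k], si[k]] <- W[ti[k], si[k]] + e$weight[k]
  }
  W
}

#' Transition matrix of a pathway network
#'
#' Entry `m[i, j]` is the normalized weight of the edge from node j to node i.
#' Under `"in_weights"` each row is divided by the node's total in-weight, so
#' rows of nodes with at least one in-edge sum to 1 and rows of in-degree-0
#' nodes are all zero. Under `"out_weights"` each column is divided by the
#' source node's total out-weight (columns of out-degree-0 nodes redistribute
#' uniformly over all nodes, the standard dangling-node fix), making the
#' matrix column-stochastic.
#'
#' @param net A `pathway_network`.
#' @param normalization `"in_weights"` or `"out_weights"`.
#' @return An n x n matrix with node names on both dimensions.
#' @export
transition_matrix <- function(net, normalization = c("in_weights", "out_weights")) {
  normalization <- match.arg(normalization)
  W <- .pair_weight_matrix(net)
  n <- nrow(W)
  if (normalization == "in_weights") {
    rs <- rowSums(W)
    keep <- rs > 0
    W[keep, ] <- W[keep, , drop = FALSE] / rs[keep]
    W
  } else {
    cs <- colSums(W)
    M <- W
    for (j in seq_len(n)) {
      if (cs[j] > 0) M[, j] <- W[, j] / cs[j] else M[, j] <- 1 / n
    }
    M
  }
}

#' Rank network nodes by the damped weighted-PageRank iteration
#'
#' Iterates `R <- d * M %*% R + (1 - d) / n` from the uniform vector
#' `R = (1/n, ..., 1/n)` until the change between successive vectors drops
#' below the configured tolerance (in the configured norm) or the iteration
#' cap is hit. The NR values are reported exactly as the fixed point of this
#' recurrence — unrescaled — since those are the values the ranking sorts.
#' Nodes with no in-edges (under `"in_weights"`) receive exactly
#' `(1 - d) / n`.
#'
#' @param net A `pathway_network`.
#' @param config A [rank_config()].
#' @return A `node_rank_result`: list with `values` (named numeric, NR value
#'   per node), `iterations`, `final_residual`, `converged` (logical),
#'   `ranking` (node ids by NR descending, ties by node id ascending) and the
#'   `config` used. Non-convergence is flagged, not an error.
#' @export
#' @examples
#' pw <- new_pathway("p", c("A", "B"), c("B", "A"), c("1.2.1.1", "4.1.1.1"))
#' node_rank(build_network(pw))$values
node_rank <- function(net, config = rank_config()) {
  if (length(net$nodes) == 0L) {
    stop_stpath("cannot rank an empty network", "stpath_domain_error")
  }
  M <- transition_matrix(net, config$normalization)
  n <- nrow(M)
  d <- config$damping
  teleport <- (1 - d) / n
  R <- rep(1 / n, n)
  resid <- Inf
  iter <- 0L
  converged <- FALSE
  # each pass computes the update R' = d M R + (1-d)/n and tests |R' - R|;
  # on convergence the *tested* vector R is returned, so the reported
  # residual is exactly its fixed-point defect
  while (iter < config$max_iterations) {
    Rn <- as.vector(d * (M %*% R)) + teleport
    resid <- switch(config$norm,
                    L1 = sum(abs(Rn - R)),
                    Linf = max(abs(Rn - R)))
    iter <- iter + 1L
    if (resid < config$tolerance) {
      converged <- TRUE
      break
    }
    R <- Rn
  }
  if (!converged) R <- Rn
  values <- stats::setNames(R, rownames(M))
  ord <- order(-values, names(values), method = "radix")
  structure(list(values = values,
                 iterations = iter,
                 final_residual = resid,
                 converged = converged,
                 ranking = names(values)[ord],
                 config = config),
            class = "node_rank_result")
}

#' @export
print.node_rank_result <- function(x, ...) {
  cat(sprintf("<node_rank_result> %d nodes, %d iterations, residual %.3g (%s)\n",
              length(x$values), x$iterations, x$final_residual,
              if (x$converged) "converged" else "NOT converged"))
  top <- utils::head(x$ranking, 5L)
  cat("  top:", paste(sprintf("%s=%.5g", top, x$values[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a node ranking
#'
#' @param result A `node_rank_result`.
#' @param top_k Optional truncation; must be positive. Values larger than the
#'   node count return the full list.
#' @return A data frame with columns `rank`, `node`, `nr_value`, sorted by NR
#'   descending with ties broken by node id.
#' @export
rank_nodes <- function(result, top_k = NULL) {
  if (!is.null(top_k)) {
    if (!is.numeric(top_k) || top_k <= 0) {
      stop_stpath("top_k must be a positive integer", "stpath_domain_error")
    }
    top_k <- as.integer(top_k)
  }
  nodes <- result$ranking
  if (!is.null(top_k)) nodes <- utils::head(nodes, top_k)
  data.frame(rank = seq_along(nodes),
             node = nodes,
             nr_value = unname(result$values[nodes]),
             stringsAsFactors = FALSE)
}

#' Per-node total in- and out-weights of a network
#' @param net A `pathway_network`.
#' @return A data frame with columns `node`, `in_weight`, `out_weight`.
#' @export
node_weights <- function(net) {
  W <- .pair_weight_matrix(net)
  data.frame(node = rownames(W),
             in_weight = unname(rowSums(W)),
             out_weight = unname(colSums(W)),
             stringsAsFactors = FALSE)
}

#' Write a node ranking to TSV
#'
#' Columns: `rank`, `node`, `nr_value`, `in_weight`, `out_weight`. Run
#' metadata (damping, tolerance, norms, iterations, residual) can be written
#' to a JSON sidecar.
#'
#' @param result A `node_rank_result`.
#' @param net The network the result was computed on.
#' @param file Output TSV path.
#' @param top_k Optional truncation, see [rank_nodes()].
#' @param meta_file Optional path for a JSON metadata sidecar.
#' @return The TSV path, invisibly.
#' @export
write_rank_tsv <- function(result, net, file, top_k = NULL, meta_file = NULL) {
  tab <- rank_nodes(result, top_k)
  w <- node_weights(net)
  tab <- merge(tab, w, by = "node", sort = FALSE)
  tab <- tab[order(tab$rank), c("rank", "node", "nr_value", "in_weight", "out_weight")]
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(meta_file)) {
    meta <- list(damping = result$config$damping,
                 tolerance = result$config$tolerance,
                 max_iterations = result$config$max_iterations,
                 normalization = result$config$normalization,
                 norm = result$config$norm,
                 iterations = result$iterations,
                 final_residual = result$final_residual,
                 converged = result$converged,
                 n_nodes = length(result$values))
    jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(file)
}
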