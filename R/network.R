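# Directed weighted pathway networks: merge pathways, annotate edges with
# ST codes and level-1 categories, export/import GraphML and JSON node-link.

#' Merge pathways into a directed weighted network
#'
#' Builds one network from a set of pathways: nodes are entities, and there is
#' one edge per distinct (source, target, ST code) triple. Parallel edges
#' between the same node pair with different ST codes are kept distinct. Each
#' edge carries its level-1 category digit (1..6) — the convention used to
#' color interactions by the cellular location where they occur — and its
#' action-type (level-2) label, e.g. "Ubiquitination" for a 4.5.x.x code.
#'
#' Under the default `"multiplicity"` weighting an edge's weight is the number
#' of distinct supporting pathway ids, so interactions recurring across
#' pathways weigh more; `"unit"` gives every edge weight 1 (an unweighted
#' analysis).
#'
#' @param pathways A single `st_pathway` or a list of them.
#' @param weight_scheme `"multiplicity"` (default) or `"unit"`.
#' @return A `pathway_network`: list with `nodes` (sorted character vector),
#'   `edges` (data frame `source`, `target`, `st_code`, `weight`, `category`,
#'   `category_label`, `pathways` — supporting ids, semicolon-joined) and
#'   `weight_scheme`. Edge order is canonical (sorted), so the result is
#'   independent of the order of the input list.
#' @export
#' @examples
#' pw <- new_pathway("p1", c("A", "B"), c("B", "C"), c("1.2.1.1", "4.1.1.1"))
#' net <- build_network(pw)
#' net$edges
build_network <- function(pathways, weight_scheme = c("multiplicity", "unit")) {
  weight_scheme <- match.arg(weight_scheme)
  if (inherits(pathways, "st_pathway")) pathways <- list(pathways)
  if (length(pathways) == 0L) {
    stop_stpath("build_network needs at least one pathway", "stpath_domain_error")
  }
  ph <- vapply(pathways, function(p) isTRUE(attr(p, "placeholder")), logical(1))
  if (any(ph) && !all(ph)) {
    warning("mixing pathways with named and placeholder entities", call. = FALSE)
  }
  steps <- do.call(rbind, lapply(pathways, function(pw) {
    data.frame(pathway_id = pw$id, pw$steps, stringsAsFactors = FALSE)
  }))
  key <- paste(steps$source, steps$target, steps$st_code, sep = "\x1f")
  groups <- split(steps$pathway_id, key)
  uniq <- steps[!duplicated(key), c("source", "target", "st_code")]
  uniq_key <- paste(uniq$source, uniq$target, uniq$st_code, sep = "\x1f")
  support <- lapply(groups[uniq_key], function(ids) sort(unique(ids)))
  uniq$weight <- if (weight_scheme == "multiplicity") {
    vapply(support, length, integer(1))
  } else {
    rep(1L, nrow(uniq))
  }
  uniq$weight <- as.numeric(uniq$weight)
  labs <- t(vapply(uniq$st_code, function(s) category_labels(s),
                   c(level1 = "", level2 = "")))
  uniq$category <- vapply(strsplit(uniq$st_code, ".", fixed = TRUE),
                          function(f) as.integer(f[1]), integer(1))
  uniq$category_label <- unname(labs[, "level2"])
  uniq$pathways <- vapply(support, paste, character(1), collapse = ";")
  ord <- order(uniq$source, uniq$target, uniq$st_code, method = "radix")
  edges <- uniq[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = sort(unique(c(edges$source, edges$target)), method = "radix"),
    edges = edges,
    weight_scheme = weight_scheme
  ), class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %d nodes, %d edges (weights: %s)\n",
              length(x$nodes), nrow(x$edges), x$weight_scheme))
  invisible(x)
}

# rebuild a canonical pathway_network from an edge data frame
.network_from_edges <- function(edges, weight_scheme = "multiplicity") {
  need <- c("source", "target", "st_code", "weight", "category",
            "category_label", "pathways")
  edges <- edges[, need, drop = FALSE]
  edges$weight <- as.numeric(edges$weight)
  edges$category <- as.integer(edges$category)
  ord <- order(edges$source, edges$target, edges$st_code, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = sort(unique(c(edges$source, edges$target)), method = "radix"),
    edges = edges,
    weight_scheme = weight_scheme
  ), class = "pathway_network")
}

#' Convert a pathway network to an igraph graph
#' @param net A `pathway_network`.
#' @return A directed `igraph` graph with the edge attributes `st_code`,
#'   `weight`, `category`, `category_label`, `pathways`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Export a pathway network to GraphML
#'
#' Writes the network with all edge attributes declared as GraphML keys;
#' [import_graphml()] reads it back to an equal network.
#'
#' @param net A `pathway_network`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
export_graphml <- function(net, file) {
  if (nrow(net$edges) == 0L) {
    stop_stpath("cannot export an empty network", "stpath_domain_error")
  }
  igraph::write_graph(as_igraph(net), file, format = "graphml")
  invisible(file)
}

#' Import a pathway network from GraphML
#' @param file A GraphML file written by [export_graphml()].
#' @param weight_scheme Weight scheme label to record on the result.
#' @return A `pathway_network`.
#' @export
import_graphml <- function(file, weight_scheme = "multiplicity") {
  g <- igraph::read_graph(file, format = "graphml")
  ends <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(source = ends[, 1], target = ends[, 2],
                      st_code = igraph::edge_attr(g, "st_code"),
                      weight = igraph::edge_attr(g, "weight"),
                      category = igraph::edge_attr(g, "category"),
                      category_label = igraph::edge_attr(g, "category_label"),
                      pathways = igraph::edge_attr(g, "pathways"),
                      stringsAsFactors = FALSE)
  .network_from_edges(edges, weight_scheme)
}

#' Export a pathway network as a JSON node-link document
#'
#' Structure: `{"nodes": [{"id": ...}], "links": [{"source", "target",
#' "st_code", "weight", "category", "category_label", "pathways"}]}`.
#'
#' @param net A `pathway_network`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
export_json <- function(net, file) {
  if (nrow(net$edges) == 0L) {
    stop_stpath("cannot export an empty network", "stpath_domain_error")
  }
  doc <- list(
    directed = TRUE,
    weight_scheme = net$weight_scheme,
    nodes = data.frame(id = net$nodes, stringsAsFactors = FALSE),
    links = net$edges
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Import a pathway network from a JSON node-link document
#' @param file A JSON file written by [export_json()].
#' @return A `pathway_network`.
#' @export
import_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  .network_from_edges(as.data.frame(doc$links, stringsAsFactors = FALSE),
                      if (!is.null(doc$weight_scheme)) doc$weight_scheme
                      else "multiplicity")
}
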