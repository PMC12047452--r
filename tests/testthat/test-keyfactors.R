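# small named networks used across the blocks
star_net <- function() {
  # A, B, C all feed D
  build_network(new_pathway("s", c("A", "B", "C"), c("D", "D", "D"),
                            c("1.2.1.1", "2.3.1.1", "4.1.1.1")))
}

cycle_net <- function(n, id = "cyc") {
  nodes <- sprintf("N%02d", seq_len(n))
  build_network(new_pathway(id, nodes, c(nodes[-1], nodes[1]),
                            rep("4.1.1.1", n)))
}

test_that("transition matrix normalizes in-weights as printed", {
  # 2-cycle: single in-neighbor each, both normalizations coincide
  two <- cycle_net(2)
  M_in <- transition_matrix(two, "in_weights")
  M_out <- transition_matrix(two, "out_weights")
  expect_identical(M_in, M_out)
  expect_identical(unname(M_in["N01", "N02"]), 1)
  expect_identical(unname(M_in["N02", "N01"]), 1)

  # star: D's in-row splits 1/3 each; source rows are all zero
  M <- transition_matrix(star_net(), "in_weights")
  expect_equal(unname(M["D", c("A", "B", "C")]), rep(1 / 3, 3))
  expect_true(all(M[c("A", "B", "C"), ] == 0))

  # weighted in-edges 3 and 1 normalize to 0.75 / 0.25
  p <- list(new_pathway("p1", "A", "C", "1.2.1.1"),
            new_pathway("p2", "A", "C", "1.2.1.1"),
            new_pathway("p3", "A", "C", "1.2.1.1"),
            new_pathway("p4", "B", "C", "4.1.1.1"))
  M <- transition_matrix(build_network(p), "in_weights")
  expect_identical(unname(M["C", "A"]), 0.75)
  expect_identical(unname(M["C", "B"]), 0.25)
})

test_that("out-weight normalization is column-stochastic with uniform dangling columns", {
  M <- transition_matrix(star_net(), "out_weights")
  expect_equal(unname(colSums(M)), rep(1, 4))
  # D has no out-edges: its column redistributes uniformly
  expect_equal(unname(M[, "D"]), rep(1 / 4, 4))

  # parallel ST codes collapse to one node-pair weight before normalizing
  p <- list(new_pathway("p1", "A", "B", "4.1.1.1"),
            new_pathway("p2", "A", "B", "4.2.1.1"),
            new_pathway("p3", "A", "C", "1.2.1.1"))
  M <- transition_matrix(build_network(p), "out_weights")
  expect_identical(unname(M["B", "A"]), 2 / 3)
  expect_identical(unname(M["C", "A"]), 1 / 3)
})

test_that("directed cycles converge to the uniform fixed point 1/n", {
  for (n in c(2L, 5L, 17L)) {
    res <- node_rank(cycle_net(n))
    expect_true(res$converged)
    expect_equal(unname(res$values), rep(1 / n, n), tolerance = 1e-9)
    # all tied: ranking falls back to node-id order
    expect_identical(res$ranking, sprintf("N%02d", seq_len(n)))
  }
})

test_that("the star fixed point matches the directly solved linear system", {
  net <- star_net()
  res <- node_rank(net)
  expect_true(res$converged)
  # independent oracle: solve (I - dM) R = (1-d)/n
  M <- transition_matrix(net, "in_weights")
  n <- nrow(M)
  exact <- solve(diag(n) - 0.85 * M, rep(0.15 / n, n))
  expect_equal(unname(res$values[rownames(M)]), unname(exact), tolerance = 1e-8)
  # and the hand-derived values
  expect_equal(unname(res$values[c("A", "B", "C")]), rep(0.0375, 3))
  expect_equal(unname(res$values["D"]), 0.069375, tolerance = 1e-10)
  expect_identical(res$ranking[1], "D")
})

test_that("nodes without in-edges score exactly (1-d)/n", {
  net <- star_net()
  res <- node_rank(net)
  # exact equality with the teleport term as the recurrence computes it
  expect_identical(unname(res$values["A"]), (1 - 0.85) / 4)
  # and every NR value is at least the teleport mass
  expect_true(all(res$values >= (1 - 0.85) / 4))
})

test_that("converged runs satisfy the fixed-point residual under both normalizations", {
  cfg_pool <- list(rank_config(normalization = "in_weights"),
                   rank_config(normalization = "out_weights"),
                   rank_config(norm = "Linf"))
  scfg <- synth_config(seed = 91, n_entities = 40, n_interactions = 160,
                       n_pathways = 12, length_range = c(3L, 8L))
  net <- build_network(generate_pathways(generate_catalog(scfg), scfg))
  for (cfg in cfg_pool) {
    res <- node_rank(net, cfg)
    expect_true(res$converged)
    M <- transition_matrix(net, cfg$normalization)
    n <- length(res$values)
    R <- res$values[rownames(M)]
    defect <- abs(R - (cfg$damping * as.vector(M %*% R) + (1 - cfg$damping) / n))
    # fixed-point verification in the configured convergence norm
    resid <- switch(cfg$norm, L1 = sum(defect), Linf = max(defect))
    expect_lt(resid, cfg$tolerance)
  }
})

test_that("rank sum is conserved under the column-stochastic variant", {
  scfg <- synth_config(seed = 13, n_entities = 25, n_interactions = 90,
                       n_pathways = 10)
  net <- build_network(generate_pathways(generate_catalog(scfg), scfg))
  res <- node_rank(net, rank_config(normalization = "out_weights"))
  expect_true(res$converged)
  expect_equal(sum(res$values), 1, tolerance = 1e-7)
})

test_that("the result is independent of node insertion order", {
  p1 <- new_pathway("p1", c("A", "B"), c("B", "C"), c("1.2.1.1", "4.1.1.1"))
  p2 <- new_pathway("p2", c("C", "D"), c("D", "A"), c("6.2.1.1", "2.3.1.1"))
  r_ab <- node_rank(build_network(list(p1, p2)))
  r_ba <- node_rank(build_network(list(p2, p1)))
  expect_identical(r_ab$values, r_ba$values)
  expect_identical(r_ab$ranking, r_ba$ranking)
})

test_that("ranking tabulation truncates and validates top_k", {
  res <- node_rank(star_net())
  full <- rank_nodes(res)
  expect_identical(full$node, c("D", "A", "B", "C"))
  expect_identical(full$rank, 1:4)
  expect_identical(rank_nodes(res, top_k = 2)$node, c("D", "A"))
  # top_k beyond n returns the full list
  expect_identical(nrow(rank_nodes(res, top_k = 99)), 4L)
  expect_error(rank_nodes(res, top_k = 0), class = "stpath_domain_error")
  expect_error(rank_nodes(res, top_k = -3), class = "stpath_domain_error")
})

test_that("rank TSV carries node weights and the JSON sidecar the run config", {
  net <- star_net()
  res <- node_rank(net)
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".json")
  write_rank_tsv(res, net, f, meta_file = m)
  tab <- read.delim(f)
  expect_identical(names(tab), c("rank", "node", "nr_value", "in_weight", "out_weight"))
  expect_identical(tab$node[1], "D")
  expect_equal(tab$in_weight[tab$node == "D"], 3)
  expect_equal(tab$out_weight[tab$node == "A"], 1)
  meta <- jsonlite::read_json(m, simplifyVector = TRUE)
  expect_identical(meta$damping, 0.85)
  expect_identical(meta$tolerance, 1e-8)
  expect_true(meta$converged)
})

test_that("degenerate configs and empty networks are rejected", {
  expect_error(rank_config(damping = 1), class = "stpath_domain_error")
  expect_error(rank_config(damping = 0), class = "stpath_domain_error")
  expect_error(rank_config(tolerance = 0), class = "stpath_domain_error")
  net <- star_net()
  net$nodes <- character(0)
  net$edges <- net$edges[0, ]
  expect_error(node_rank(net), class = "stpath_domain_error")
})
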