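edges_to_net <- function(edges, isolated = character(0)) {
  # wrap a plain weighted edge list as a pcor_network for the detection API
  nodes <- unique(c(edges$from, edges$to, isolated))
  p <- length(nodes)
  pc <- diag(p); dimnames(pc) <- list(nodes, nodes)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$from[k], nodes); j <- match(edges$to[k], nodes)
    pc[i, j] <- pc[j, i] <- edges$weight[k]
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = edges$from, to = edges$to,
                                    pcor = edges$weight),
                 pcor = pc, isolated = isolated), class = "pcor_network")
}

test_that("Louvain recovers the two cliques and matches exhaustive search", {
  fx <- load_fixture("two_cliques_bridge")
  net <- edges_to_net(fx$edges)
  part <- louvain_communities(net, weight_mode = "binary", seed = 1)
  expect_equal(part$n_communities, 2)
  ari <- adjusted_rand_index(part$membership[names(fx$expected_partition)],
                             fx$expected_partition)
  expect_equal(ari, 1)
  expect_equal(part$modularity, fx$expected_q, tolerance = 1e-12)
  brute <- brute_force_modularity(fx$edges, net$nodes)
  expect_equal(part$modularity, brute$q, tolerance = 1e-12)
})

test_that("modularity formula: hand-evaluated cases and bounds", {
  # single edge, one community: Q = 0
  e1 <- data.frame(from = "a", to = "b", weight = 1)
  expect_equal(modularity_q(e1, c(a = 1, b = 1)), 0)
  # two disconnected unit edges, each its own community: Q = 0.5
  e2 <- data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1)
  expect_equal(modularity_q(e2, c(a = 1, b = 1, c = 2, d = 2)), 0.5)
  # matches igraph's implementation on a weighted graph (dual route)
  fx <- load_fixture("two_cliques_bridge")
  g <- igraph::graph_from_data_frame(fx$edges, directed = FALSE)
  memb <- setNames(c(1, 1, 2, 2, 1, 2, 1, 2)[match(igraph::V(g)$name,
                                                   paste0("n", 1:8))],
                   igraph::V(g)$name)
  expect_equal(modularity_q(fx$edges, memb),
               igraph::modularity(g, memb, weights = fx$edges$weight),
               tolerance = 1e-12)
  # any partition stays within [-0.5, 1]
  for (pp in set_partitions(4)) {
    q <- modularity_q(e2, setNames(pp, c("a", "b", "c", "d")))
    expect_true(q >= -0.5 && q <= 1)
  }
})

test_that("Louvain never loses to the trivial partition; edgeless errors", {
  fx <- load_fixture("two_cliques_bridge")
  net <- edges_to_net(fx$edges)
  for (s in 1:5) {
    part <- louvain_communities(net, weight_mode = "binary", seed = s)
    expect_gte(part$modularity, 0)
  }
  empty <- structure(list(nodes = c("a", "b"),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             pcor = numeric(0)),
                          pcor = diag(2), isolated = c("a", "b")),
                     class = "pcor_network")
  expect_error(louvain_communities(empty), "no edges")
})

test_that("eigenvector centrality: star closed form, K4 symmetry, oracle", {
  fx <- load_fixture("star4_centrality")
  net <- edges_to_net(fx$edges)
  ec <- eigenvector_centrality(net)
  expect_equal(ec[names(fx$expected)], fx$expected, tolerance = 1e-9)
  # complete graph: all scores 1
  k4 <- t(utils::combn(letters[1:4], 2))
  net4 <- edges_to_net(data.frame(from = k4[, 1], to = k4[, 2], weight = 1))
  expect_equal(unname(eigenvector_centrality(net4)), rep(1, 4))
  # dense eigensolver oracle on a random weighted graph
  set.seed(9)
  pairs <- t(utils::combn(6, 2))
  keep <- sample(nrow(pairs), 10)
  edges <- data.frame(from = paste0("v", pairs[keep, 1]),
                      to = paste0("v", pairs[keep, 2]),
                      weight = runif(10, 0.1, 1))
  netr <- edges_to_net(edges)
  ec2 <- eigenvector_centrality(netr)
  A <- edges_to_adjacency(edges, netr$nodes)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    A > 0, mode = "undirected"))
  for (k in seq_len(comp$no)) {
    mem <- names(comp$membership)[comp$membership == k]
    if (length(mem) < 2) next
    v <- abs(eigen(A[mem, mem], symmetric = TRUE)$vectors[, 1])
    expect_equal(unname(ec2[mem]), v / max(v), tolerance = 1e-8)
  }
  # invariance to uniform edge-weight rescaling
  edges10 <- transform(edges, weight = weight * 10)
  expect_equal(eigenvector_centrality(edges_to_net(edges10)), ec2,
               tolerance = 1e-9)
  # isolated nodes score zero
  netiso <- edges_to_net(edges, isolated = "z")
  expect_equal(unname(eigenvector_centrality(netiso)["z"]), 0)
})

test_that("central nodes: hub of a star, ties broken lexicographically", {
  fx <- load_fixture("star4_centrality")
  net <- edges_to_net(fx$edges)
  part <- louvain_communities(net, weight_mode = "binary", seed = 1)
  ec <- eigenvector_centrality(net)
  cn <- central_nodes(part, ec)
  expect_equal(unname(cn["c1"]), "hub")
  # symmetric pair: lexicographic tie-break with warning
  e <- data.frame(from = "b", to = "a", weight = 1)
  net2 <- edges_to_net(e)
  part2 <- louvain_communities(net2, weight_mode = "binary", seed = 1)
  ec2 <- eigenvector_centrality(net2)
  expect_warning(cn2 <- central_nodes(part2, ec2), "tie")
  expect_equal(unname(cn2), "a")
  # singleton community
  part3 <- structure(list(membership = c(x = 1L), isolated = character(0),
                          n_communities = 1L), class = "community_partition")
  expect_equal(unname(central_nodes(part3, c(x = 0.4))), "x")
})

test_that("partition export lists every node with its isolation flag", {
  fx <- load_fixture("two_cliques_bridge")
  net <- edges_to_net(fx$edges, isolated = "lonely")
  part <- louvain_communities(net, weight_mode = "binary", seed = 1)
  ec <- eigenvector_centrality(net)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(net, part, ec, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 9)
  expect_true(df$is_isolated[df$node == "lonely"])
  expect_true(is.na(df$community[df$node == "lonely"]))
})
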