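test_that("Louvain recovers planted structure and Q matches the modularity formula", {
  # two cliques joined by one weak edge
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1; a[5:8, 5:8] <- 1; diag(a) <- 0
  a[4, 5] <- a[5, 4] <- 0.1
  g <- graph_from_adj(a)
  part <- detect_communities(g, seed = 1)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:4])), 1)
  expect_equal(length(unique(part$membership[5:8])), 1)
  expect_equal(part$modularity,
               oracle_modularity(a, part$membership), tolerance = 1e-12)

  # planted-partition toy graph: exact recovery up to relabeling
  gp <- generate_toy_graph("planted_partition", 12, p_in = 0.9, p_out = 0.05,
                           seed = 3)
  pp <- detect_communities(gp, seed = 2)
  tab <- table(igraph::V(gp)$block, pp$membership)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  ap <- igraph::as_adjacency_matrix(gp, attr = "weight", sparse = FALSE)
  expect_equal(pp$modularity, oracle_modularity(ap, pp$membership),
               tolerance = 1e-12)
})

test_that("a uniform complete graph yields a single community", {
  part <- detect_communities(generate_toy_graph("complete", 6), seed = 1)
  expect_equal(length(unique(part$membership)), 1)
  expect_lte(part$modularity, 0)
})

test_that("an edgeless graph puts every node in its own community with Q = 0", {
  g0 <- graph_from_adj(matrix(0, 5, 5))
  part <- detect_communities(g0)
  expect_equal(length(unique(part$membership)), 5)
  expect_equal(part$modularity, 0)
})

test_that("community detection is reproducible given a seed", {
  set.seed(99)
  a <- random_adjacency(15, 0.4)
  g <- graph_from_adj(a)
  expect_identical(detect_communities(g, seed = 42)$membership,
                   detect_communities(g, seed = 42)$membership)
})

test_that("diversity is the Shannon entropy of the neighbour community distribution", {
  # center v1 with 4 neighbours in communities (A, A, B, C): p = (.5,.25,.25)
  st <- generate_toy_graph("star", 5)
  part <- structure(list(
    membership = c(v1 = 9L, v2 = 1L, v3 = 1L, v4 = 2L, v5 = 3L),
    modularity = 0), class = "community_partition")
  h <- diversity_scores(st, part)
  expect_equal(unname(h["v1"]), 1.5)      # -(.5 log2 .5 + 2 * .25 log2 .25)
  expect_equal(unname(h["v2"]), 0)        # single-community neighbourhood

  # 2 + 2 neighbours over 2 communities -> 1 bit
  st5 <- generate_toy_graph("star", 5)
  part2 <- structure(list(
    membership = c(v1 = 9L, v2 = 1L, v3 = 1L, v4 = 2L, v5 = 2L),
    modularity = 0), class = "community_partition")
  expect_equal(unname(diversity_scores(st5, part2)["v1"]), 1)

  # isolated node scores 0
  g <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  p3 <- structure(list(membership = stats::setNames(c(1L, 2L, 3L),
                                                    igraph::V(g)$name),
                       modularity = 0), class = "community_partition")
  expect_equal(unname(diversity_scores(g, p3)[3]), 0)
})

test_that("diversity is invariant to community relabeling", {
  set.seed(5)
  a <- random_adjacency(10, 0.5)
  g <- graph_from_adj(a)
  part <- detect_communities(g, seed = 1)
  relab <- part
  shuffle <- sample(100, length(unique(part$membership)))
  relab$membership <- stats::setNames(
    shuffle[match(part$membership, unique(part$membership))],
    names(part$membership))
  expect_equal(diversity_scores(g, part), diversity_scores(g, relab))
})

test_that("role taxonomy crosses hub and connector flags with inclusive ties", {
  nodes <- paste0("r", 1:21)
  hub <- stats::setNames(seq(0.01, 1, length.out = 21), nodes)
  div <- stats::setNames(c(seq(2, 0.1, length.out = 20), 2.5), nodes)
  roles <- classify_node_roles(hub, div, quantile = 0.20)
  expect_equal(sum(roles$is_hub), 5)        # ceiling(0.2 * 21)
  expect_equal(sum(roles$is_connector), 5)
  # r21: top hub score and top diversity
  expect_equal(roles$role[roles$node == "r21"], "ConnectorHub")
  # r20: top-5 hub score but low diversity
  expect_equal(roles$role[roles$node == "r20"], "ProvincialHub")
  # r1: bottom hub score, top diversity
  expect_equal(roles$role[roles$node == "r1"], "NonHubConnector")
  expect_equal(roles$role[roles$node == "r10"], "Peripheral")
  expect_true(all(table(roles$role)[c("ConnectorHub", "ProvincialHub")] > 0))
  # every node gets exactly one role
  expect_equal(nrow(roles), 21)
  expect_true(all(roles$role %in% c("ConnectorHub", "ProvincialHub",
                                    "NonHubConnector", "Peripheral")))
})
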