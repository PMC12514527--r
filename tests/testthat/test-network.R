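test_that("Spearman rho equals Pearson on midranks (oracle) and handles sign cases", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  ts <- roi_timeseries("a", "g", rbind(A = x, B = y, C = 2 * x + 1,
                                       D = -x^3),
                       bin_edges = c(0, 5))
  cm <- build_spearman_matrix(ts, 1)
  # oracle: Pearson correlation of the rank vectors
  expect_equal(cm$rho["A", "B"], stats::cor(rank(x), rank(y)))
  expect_equal(cm$rho["A", "B"], 0.8)
  expect_equal(cm$rho["A", "C"], 1)   # strictly increasing map
  expect_equal(cm$rho["A", "D"], -1)  # strictly decreasing map
  expect_equal(cm$m, choose(4, 2))
  expect_true(isSymmetric(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))
})

test_that("Spearman agrees with the rank-then-Pearson oracle to 10+ digits", {
  set.seed(81)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    x <- matrix(stats::rnorm(5 * n), 5)
    rownames(x) <- paste0("r", 1:5)
    cm <- build_spearman_matrix(roi_timeseries("a", "g", x, c(0, n)), 1)
    oracle <- stats::cor(apply(t(x), 2, rank))
    expect_equal(cm$rho, oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("exact and t-approximate Spearman p-values agree for small untied samples", {
  set.seed(4)
  x <- matrix(stats::rnorm(2 * 8), 2, dimnames = list(c("A", "B"), NULL))
  ts <- roi_timeseries("a", "g", x, c(0, 8))
  p_t <- build_spearman_matrix(ts, 1, p_method = "t")$p_raw["A", "B"]
  p_ex <- build_spearman_matrix(ts, 1, p_method = "exact")$p_raw["A", "B"]
  expect_lt(abs(p_t - p_ex), 0.1)
})

test_that("degenerate inputs produce informative errors", {
  x <- rbind(A = rep(3, 10), B = stats::rnorm(10))
  ts <- roi_timeseries("a", "g", x, c(0, 10))
  expect_error(build_spearman_matrix(ts, 1), "zero-variance.*A")
  expect_error(build_spearman_matrix(ts, 3), "out of range")
  expect_error(roi_timeseries("a", "g", x, c(0, 4, 9)), "bin_edges")
})

test_that("thresholding keeps only positive, Bonferroni-significant pairs", {
  nodes <- paste0("r", 1:21)
  rho <- sym_matrix(nodes, 0.5); diag(rho) <- 1
  p <- sym_matrix(nodes, 0.5); diag(p) <- NA
  cm <- make_cm(rho, p)
  expect_equal(cm$m, 210)  # Bonferroni family: C(21, 2)
  g <- threshold_to_network(cm)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 21)  # isolated nodes retained

  # strong negative correlation never becomes an edge
  rho2 <- rho; p2 <- p
  rho2["r1", "r2"] <- rho2["r2", "r1"] <- -0.9
  p2["r1", "r2"] <- p2["r2", "r1"] <- 1e-9
  expect_equal(igraph::ecount(threshold_to_network(make_cm(rho2, p2))), 0)

  # p_raw = 1e-5 with m = 210 -> p_adj = 2.1e-3, not significant at 0.001
  rho3 <- rho; p3 <- p
  p3["r1", "r2"] <- p3["r2", "r1"] <- 1e-5
  expect_equal(igraph::ecount(threshold_to_network(make_cm(rho3, p3))), 0)
  expect_equal(igraph::ecount(threshold_to_network(make_cm(rho3, p3),
                                                   alpha = 0.01)), 1)
})

test_that("edge sets are monotone in alpha", {
  set.seed(12)
  nodes <- paste0("r", 1:10)
  rho <- sym_matrix(nodes); p <- sym_matrix(nodes, NA)
  for (i in 1:9) for (j in (i + 1):10) {
    rho[i, j] <- rho[j, i] <- stats::runif(1, -1, 1)
    p[i, j] <- p[j, i] <- stats::runif(1, 0, 0.2 / 45)
  }
  diag(rho) <- 1
  cm <- make_cm(rho, p)
  alphas <- c(0.0005, 0.001, 0.01, 0.05, 0.2)
  edge_ids <- lapply(alphas, function(a)
    apply(igraph::as_edgelist(threshold_to_network(cm, a)), 1, paste,
          collapse = "-"))
  for (k in seq_len(length(alphas) - 1))
    expect_true(all(edge_ids[[k]] %in% edge_ids[[k + 1]]))
})

test_that("consensus retains edges by fraction and averages significant weights", {
  nodes <- c("A", "B", "C")
  mk <- function(ab_rho, ab_sig, bc_sig = FALSE) {
    rho <- sym_matrix(nodes, 0); diag(rho) <- 1
    p <- sym_matrix(nodes, 0.9); diag(p) <- NA
    rho["A", "B"] <- rho["B", "A"] <- ab_rho
    if (ab_sig) p["A", "B"] <- p["B", "A"] <- 1e-9
    if (bc_sig) { rho["B", "C"] <- rho["C", "B"] <- 0.4
                  p["B", "C"] <- p["C", "B"] <- 1e-9 }
    threshold_to_network(make_cm(rho, p))
  }
  w <- c(0.5, 0.6, 0.7, 0.8, 0.6, 0.4)
  nets <- c(lapply(w, mk, ab_sig = TRUE),
            list(mk(0.3, FALSE), mk(0.2, FALSE)))

  cg <- build_consensus_network(nets, min_fraction = 0.75)
  el <- igraph::as_data_frame(cg)
  expect_equal(nrow(el), 1)  # A-B in 6/8 = 0.75 retained, B-C in 0/8 absent
  expect_equal(el$weight, mean(w))  # mean over significant occurrences only
  expect_equal(el$retention_fraction, 0.75)

  # at 5/8 the edge is dropped
  nets5 <- c(lapply(w[1:5], mk, ab_sig = TRUE),
             lapply(1:3, function(i) mk(0.3, FALSE)))
  expect_equal(igraph::ecount(build_consensus_network(nets5, 0.75)), 0)
})

test_that("consensus edge set shrinks as min_fraction grows and node sets must match", {
  set.seed(33)
  nets <- lapply(1:6, function(k) {
    a <- random_adjacency(7, p = 0.5)
    rownames(a) <- colnames(a) <- paste0("r", 1:7)
    graph_from_adj(a)
  })
  counts <- vapply(c(0.3, 0.5, 0.8, 1),
                   function(f) igraph::ecount(build_consensus_network(nets, f)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  bad <- nets
  igraph::V(bad[[2]])$name <- paste0("x", 1:7)
  expect_error(build_consensus_network(bad), "mismatched")
})

test_that("networks round-trip through GraphML", {
  set.seed(2)
  a <- random_adjacency(6, 0.6)
  rownames(a) <- colnames(a) <- paste0("v", 1:6)
  g <- graph_from_adj(a)
  dir <- withr::local_tempdir()
  write_network(g, file.path(dir, "g.graphml"), file.path(dir, "g.csv"))
  g2 <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  a2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(a2[rownames(a), colnames(a)], a, tolerance = 1e-9)
  el <- utils::read.csv(file.path(dir, "g.csv"))
  expect_identical(names(el)[1:3], c("source", "target", "weight"))
})
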