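# Brute-force oracles, independent of the package's igraph-backed code paths.
# All operate on a weighted adjacency matrix `a` (symmetric, zero diagonal),
# with shortest-path length 1/weight per edge, and are only meant for tiny n.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && a[i, j] > 0) d[i, j] <- 1 / a[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_transitivity <- function(a) {
  bin <- a > 0
  n <- nrow(a)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k && bin[i, j] && bin[j, k] && bin[i, k])
      triangles <- triangles + 1
  }
  for (center in seq_len(n)) {
    deg <- sum(bin[center, ])
    triples <- triples + choose(deg, 2)
  }
  if (triples == 0) 0 else 3 * triangles / triples
}

oracle_hub_scores <- function(a, iters = 5000) {
  if (all(a == 0)) return(rep(0, nrow(a)))
  # shift by the max row sum so every eigenvalue is positive: power iteration
  # then converges to the Perron vector even on bipartite components
  shifted <- a + diag(max(rowSums(a)), nrow(a))
  v <- rep(1, nrow(a))
  for (i in seq_len(iters)) {
    v2 <- shifted %*% v
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) return(rep(0, nrow(a)))
    v <- as.numeric(v2 / nrm)
  }
  v <- abs(v)
  v[v < 1e-10 * max(v)] <- 0
  v / max(v)
}

# All shortest paths between each pair by exhaustive simple-path enumeration,
# with fractional counting of interior nodes (Brandes semantics).
oracle_betweenness <- function(a, tol = 1e-12) {
  n <- nrow(a)
  btw <- numeric(n)
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == to) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (w in seq_len(n)) {
        if (a[v, w] > 0 && !(w %in% path))
          walk(c(path, w), len + 1 / a[v, w])
      }
    }
    walk(from, 0)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    shortest <- paths[lens <= min(lens) + tol]
    for (p in shortest) {
      interior <- setdiff(p$path, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  btw
}

oracle_closeness <- function(a) {
  d <- oracle_distances(a)
  apply(d, 1, function(row) {
    fin <- is.finite(row) & row > 0
    if (!any(fin)) 0 else sum(fin) / sum(row[fin])
  })
}

# Weighted Newman-Girvan modularity evaluated directly from the formula.
oracle_modularity <- function(a, membership) {
  w_tot <- sum(a) / 2
  if (w_tot == 0) return(0)
  s <- rowSums(a)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + a[i, j] - s[i] * s[j] / (2 * w_tot)
  }
  unname(q / (2 * w_tot))
}

# Random weighted graph on n nodes as an adjacency matrix.
random_adjacency <- function(n, p = 0.5, wmin = 0.2, wmax = 1.5) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) a[i, j] <- a[j, i] <- stats::runif(1, wmin, wmax)
  }
  a
}

graph_from_adj <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("v", seq_len(nrow(a)))
  if (igraph::ecount(g) == 0)
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  g
}

# Hand-built correlation_matrix objects for threshold/consensus tests.
make_cm <- function(rho, p_raw, animal_id = "a1", group = "g", bin = 1L) {
  nodes <- rownames(rho)
  m <- nrow(rho) * (nrow(rho) - 1) / 2
  p_adj <- pmin(m * p_raw, 1)
  diag(p_adj) <- NA_real_
  structure(list(rho = rho, p_raw = p_raw, p_adj = p_adj, m = m,
                 n_samples = 100L, animal_id = animal_id, group = group,
                 bin = bin),
            class = "correlation_matrix")
}

sym_matrix <- function(nodes, fill = 0) {
  n <- length(nodes)
  matrix(fill, n, n, dimnames = list(nodes, nodes))
}

# Small null cohort (single post-injection bin) used by calibration tests.
null_cohort_networks <- function(seed) {
  co <- generate_cohort(cohort_config(seed = seed, hub_gain = 0, n_bins = 1))
  nets <- lapply(co$timeseries, function(t)
    threshold_to_network(build_spearman_matrix(t, 1)))
  grp <- vapply(co$timeseries, `[[`, character(1), "group")
  list(nets = nets, grp = grp,
       consensus_rea = build_consensus_network(nets[grp == "reactivation"]),
       consensus_ctl = build_consensus_network(nets[grp == "control"]))
}
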